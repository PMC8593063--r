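---
title: "Modelling arterial-wall microstructure from multi-shell diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arterial-wall microstructure from multi-shell diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arterydmri)
```

## The problem

The media of an artery is dominated by circumferentially aligned smooth
muscle cells wrapped in collagen. Water diffusing through that
microenvironment is hindered anisotropically, and the departure of its
diffusion-weighted MR signal from a single Gaussian (mono-exponential)
decay carries information about the tissue's composition: removing
collagen (collagenase digestion) or removing the cells (decellularization)
changes the decay in characteristic ways. `arterydmri` implements the
quantitative chain needed to study this with multi-shell diffusion MRI:
acquisition-scheme construction, a synthetic arterial-ring phantom,
redundancy-based noise estimation with Rician bias removal, Gaussian and
non-Gaussian signal modelling along the tensor eigenframe, scalar
microstructure indices, and group statistics.

Everything operates on two acquisition designs. The *high multi b-value*
(HMb) protocol has twelve shells at b = 100–3000 s/mm² with 12
directions per shell and 121 interleaved b0 scans; it drives the
directional (per-eigenvector) modelling. The *high angular resolution*
(HAR) protocol has three shells (800/1600/2200 s/mm²) with 96 directions
per shell plus polarity reversal and 60 b0 scans; it drives the kurtosis
tensor and a DTI comparator. Both use pulse timings δ = 3.55 ms,
Δ = 8.52 ms, so the effective diffusion time is τ = Δ − δ/3 ≈ 7.34 ms.

## Signal models

For a decay `S(b)/S(0)` sampled along one axis the package fits four
representations:

* **Mono-exponential**: `ln S(b)/S(0) ≈ −b D_app`. Fitted log-linearly,
  then refined by box-constrained Levenberg–Marquardt with `D_app ≥ 0`.
* **Stretched exponential**: `S(b)/S(0) = exp(−b^α D_st)` with the
  heterogeneity index `α ∈ [0.1, 1]`. Initialised from the
  mono-exponential solution at α = 1 (numerically, a hair inside the
  bound — a Levenberg–Marquardt step cannot leave a start placed exactly
  on an active bound).
* **Kurtosis**: `ln S(b)/S(0) ≈ −b D_app + b² D_app² K_app / 6`,
  restricted to b ≤ 2400 s/mm², with `K_app ≥ 0`. Initialised by a
  quadratic log-linear fit.
* **Bi-exponential**: `S(b)/S(0) = v_f e^(−D_f b) + v_s e^(−D_s b)` with
  `v_f + v_s = 1` and `D_f ≥ D_s ≥ 0`. Initialised segment-wise — fast
  slope from b ≤ 900, slow slope and `v_f = 1 − exp(intercept)` (clipped
  to [0.05, 0.95]) from b ≥ 1800 — and refined over
  `(v_f, D_s, D_f − D_s)` so the ordering constraint is structural rather
  than penalised. When the two rates collapse (difference below
  10⁻⁶ mm²/s) or `v_f` reaches 1 the slow compartment is unidentifiable
  and the fit reports `v_f = 1`, `D_s = D_f` with a degeneracy flag,
  avoiding arbitrary fraction splits.

All non-linear refinements use `minpack.lm::nls.lm` with parameter and
function tolerances of 1e-10 and at most 500 iterations. The three
non-Gaussian models are nested in the mono-exponential model (α = 1,
K = 0, D_f = D_s), and the test suite verifies that fits on
mono-exponential data collapse onto the mono-exponential solution.

The voxel-wise tensor models are fit log-linearly (weighted, for the
kurtosis tensor, by the squared predicted signal in a second pass) and
the DTI fit is refined by constrained NLLS. Eigenvalues are sorted
descending; negative eigenvalues are clipped to zero and the voxel is
flagged and excluded from group statistics. The DTI fit uses b ≤ 900
s/mm² on HMb and b ≤ 800 s/mm² on HAR; the kurtosis tensor uses all HAR
shells (the shell list tops out at 2200 s/mm²).

## The directional projection

All 1-D models are fit along the DTI eigenvectors, so every model shares
the mono-exponential frame of reference. With only 12 directions per HMb
shell, reading off the nearest measured direction would be noisy, so the
package evaluates each shell's angular signal profile at the chosen
eigenvector from a fitted smooth model. The log-signal per shell is
expanded in an even basis *in the tensor eigenframe*: the three
second-order terms `u_i²` (the apparent shell tensor) plus the three
frame-aligned fourth-order terms `u_i⁴`. The quartic terms capture the
angular curvature that multi-compartment signal adds on top of a single
tensor; for single-tensor data they vanish and the projection is exact.
On noise-free two-compartment ring voxels this keeps the projected decay
within about 0.5 % of the true decay along each eigenvector (the purely
quadratic model errs by up to ~2.5 % along the tertiary axis at
b = 3000 s/mm², which corrupts the slow-compartment estimate there). The
basis needs six well-spread directions per shell, which both protocols
exceed.

## Derived indices

From the DTI eigenvalues: MD (mean eigenvalue), FA (the standard
normalised eigenvalue dispersion), and the sum-normalised Westin shape
triple `C_L = (λ1−λ2)/Σλ`, `C_P = 2(λ2−λ3)/Σλ`, `C_S = 3λ3/Σλ`, which
form barycentric coordinates for the 3P shape plot
(`plot_westin_triangle()`). From the kurtosis tensor: the apparent
kurtosis `K(n) = (MD²/D(n)²) W(n)` is averaged over a fixed seeded set of
100 approximately uniform directions for MK, over a 36-point ring
perpendicular to the principal eigenvector for RK, and evaluated at the
principal eigenvector for AK; KA is the raw standard deviation of `K(n)`
over the direction sample (the SD itself, not SD/MK — the usual verbal
definition of kurtosis anisotropy). Numerical averaging was chosen over
closed-form expressions because it mirrors those definitions directly
and is checkable against an independent oracle. TORT is reported as
`λ1 / ((λ2+λ3)/2)`, the axial-to-mean-radial diffusivity ratio; its
formula is not standardised across tools, so it is configurable in
spirit and deliberately not part of any quantitative acceptance check.
From a bi-exponential fit: `D_biexp = v_f D_f + v_s D_s` and
`K_biexp = 3 v_f v_s (D_f − D_s)² / D_biexp²`, and the displacement
scales `r = √(6Dτ)` (micrometres) that translate the fast and slow rates
into the length scales the experiment is sensitive to — about 8 µm and
3 µm for the native-tissue average rates of 1.3×10⁻³ and 0.17×10⁻³
mm²/s at τ ≈ 7.34 ms.

## Noise machinery

Noise is estimated from the inherent redundancy of multi-shell data by
local-patch MP-PCA: for each voxel, the surrounding patch (default
5×5×5, truncated at edges) by measurement matrix is eigen-decomposed and
the largest trailing eigenvalue set whose spread matches the
Marchenko–Pastur law (spread ≤ 4σ̂²√γ with γ the effective aspect ratio)
is classified as noise; the signal is rebuilt from the remaining
components and σ̂ mapped per voxel. Where the denoised signal sits below
3σ̂, the denoised magnitude is treated as a proxy for the Rician
expectation and the amplitude recovered by second-moment inversion,
`ŝ = √(max(m² − 2σ̂², 0))`. The closed-form inversion is monotone and
stable below SNR 1, unlike first-moment (Laguerre) root-finding; the
SNR < 3 gate confines it to where the bias matters. The background noise
floor is reported as the standard deviation of background magnitudes
over all b0 measurements — for a Rayleigh background this equals
σ√((4−π)/2), which the tests verify.

## The phantom

`make_phantom()` builds a ring ("media annulus") of two-compartment
anisotropic voxels whose shared eigenframe follows the circumferential
tangent, surrounded by signal-free background; Rician noise
`√((S+n₁)² + n₂²)` with σ = S0/SNR is applied everywhere, so the
background is a pure Rician floor. Voxels are media or background,
never mixed, keeping ground truth exact. Three presets encode the tissue
models at the signal level. The native preset uses the published
native-average fast/slow rates (1.3×10⁻³ / 0.17×10⁻³ mm²/s) split
anisotropically (fast eigenvalues 1.9/1.2/0.8 ×10⁻³); collagenase
multiplies the slow-compartment eigenvalues by 1.5 and relaxes the fast
anisotropy; decellularized is near-isotropic with `v_f` raised to 0.7.
Only the native averages are measured values — the remaining numbers are
synthetic anchors chosen once so that the fitted indices reproduce the
expected group orderings (FA highest in native, MD highest in
decellularized, slow diffusivity highest after collagenase, on average
about 1.5× the native slow rate).

What the phantom deliberately does *not* emulate: biological
between-sample variability ("samples" differ only by noise realisation),
relaxation weighting, exchange between compartments, partial-volume
mixing at the ring edge, and acquisition artifacts (Gibbs ringing, eddy
currents, B1 inhomogeneity) — which is also why the corresponding
third-party corrections are out of scope here; the preprocessing stage
is the natural hook point if real data need them. Passing tests
therefore demonstrate the correctness of the estimators under the
phantom's assumptions, not performance on real tissue.

## The pipeline and its statistics

`run_pipeline(pipeline_config(...))` chains simulate → denoise/bias
correct → DTI → directional extraction → non-Gaussian fits → indices →
slice-level ROI aggregation → one-way ANOVA with Tukey HSD post-hoc over
the three group pairs (significance at p < 0.05, no correction across
indices). The default design mirrors the study layout: three groups ×
three samples × four slices, one ROI per slice, i.e. n = 12 observations
per group; ROI means are the observational unit and the sample/slice
nesting is not modelled. Tukey HSD is the chosen post-hoc (the standard
ANOVA follow-up; Bonferroni would be the conservative alternative). All
randomness fans out from one top-level seed, and a rerun with the same
configuration writes byte-identical tables.

Default problem sizes are the package's own choices for a single-core
desk run: a 24×24×4 grid with ring radii 4–8 voxels, SNR 20, MP-PCA
patch radius 1 inside the pipeline, and a seeded subsample of 30 media
voxels per slice for the per-voxel non-Gaussian fits (the expensive
stage; estimates are ROI means, so subsampling adds variance but no
bias). The full default run takes roughly five minutes.

## Numerical choices and known limitations

* Degenerate inputs: all-zero tensors yield flagged missing FA;
  zero-trace tensors are rejected by the Westin decomposition; empty ROI
  masks and rank-deficient gradient designs raise classed input errors.
* The per-voxel bi-exponential NLLS estimator is skewed at finite SNR:
  on raw Rician decays at SNR 20 the group-mean fast diffusivity
  over-shoots by tens of percent. The processing chain (MP-PCA + Rician
  correction) reduces the residual group-mean bias to a few percent,
  which is what the acceptance checks quantify; per-voxel bi-exponential
  estimates on raw noisy data should not be averaged naively.
* Sorted eigenvalues are not unbiased estimators of population
  eigenvalues: at SNR 10, noise-induced eigenvalue repulsion pushes the
  sorted λ1 *up* even though the tensor estimate as a whole is deflated.
  The package's Rician-phenomenology checks therefore read the bias from
  rotation-invariant summaries (the trace and MD, biased down; FA,
  biased up; the tertiary eigenvalue, biased down).
* The directional projection assumes the fourth-order angular structure
  is aligned with the tensor eigenframe (exact for the phantom, an
  approximation for noisy eigenframes).
* The stretched exponent and `D_st` are strongly correlated on shallow
  decays; bounds keep the fit stable but confidence intervals are not
  provided.
* IVIM-style perfusion interpretation of the fast compartment, model
  selection, spatial regularisation, and tractography are out of scope.
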