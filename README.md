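# arterydmri

Gaussian and non-Gaussian diffusion-MRI modelling of arterial-wall
microstructure.

The media of an artery — circumferentially aligned smooth muscle cells
enveloped by collagen — hinders water diffusion anisotropically, and the
way its diffusion-weighted MR signal departs from a simple Gaussian decay
reflects which constituents are present. This package implements the
complete quantitative chain for studying that with multi-shell ex-vivo
diffusion MRI, for imaging scientists and vascular-biomechanics groups
who want reproducible, testable estimators rather than point-and-click
tools:

* multi-shell acquisition schemes: a 12-shell high multi b-value (HMb)
  design (b = 100–3000 s/mm², 12 directions/shell, 121 interleaved b0)
  and a 3-shell high angular resolution (HAR) design (b = 800/1600/2200
  s/mm², 96 directions/shell with polarity reversal), both with
  δ/Δ = 3.55/8.52 ms, plus seeded electrostatic-repulsion direction
  generation and NIfTI/FSL bval-bvec I/O;
* a synthetic arterial-ring phantom: two non-exchanging Gaussian
  compartments per voxel sharing a circumferential eigenframe, three
  tissue presets (native, collagenase-treated, decellularized), Rician
  noise and a signal-free background;
* noise machinery: Marchenko–Pastur PCA noise estimation/denoising,
  Rician bias removal by second-moment inversion below SNR 3, and the
  background noise floor;
* model fitting: voxel-wise DTI (b ≤ 900 s/mm² HMb, b ≤ 800 HAR) and the
  kurtosis tensor (all HAR shells), plus mono-exponential,
  stretched-exponential (α ∈ [0.1, 1]), 1-D kurtosis (b ≤ 2400) and
  bi-exponential (v_f + v_s = 1, D_f ≥ D_s) fits along the DTI
  eigenvectors, with the initialisation and box-constrained NLLS scheme
  described in the vignette;
* indices: FA, MD, Westin shapes C_L/C_P/C_S, MK/AK/RK/KA/TORT,
  D_biexp = v_f·D_f + v_s·D_s,
  K_biexp = 3·v_f·v_s·(D_f − D_s)²/D_biexp², effective diffusion time
  τ = Δ − δ/3 and displacement scales r = √(6Dτ);
* group statistics: slice-level ROI aggregation and one-way ANOVA with
  Tukey HSD post-hoc tests at p < 0.05, with `tidy()`/`glance()`
  accessors and ggplot2 plotting (`autoplot()`, `plot_decay()`,
  `plot_westin_triangle()`).

## Worked example

Simulate a native-tissue ring phantom on the HMb protocol at SNR 20,
denoise it, fit the tensor in the media, and fit the two-compartment
model along the primary eigenvector of one voxel:

```r
library(arterydmri)

scheme  <- build_hmb_scheme(seed = 1)
phantom <- make_phantom(phantom_spec("native", snr_b0 = 20, seed = 42),
                        scheme)
est <- mppca_denoise(phantom$volume, patch_radius = 1)
vol <- rician_bias_correct(dwi_volume(est$denoised, scheme,
                                      phantom$volume$voxel_size), est)

tensors <- fit_dti(vol, bmax = 900, mask = phantom$media_mask)
fa_md(cbind(tensors$l1, tensors$l2, tensors$l3)) |>
  dplyr::summarise(FA = mean(FA), MD = mean(MD))
#>      FA       MD
#> 1 0.368 0.000620

decay <- extract_directional_decay(vol, tensors[1, ], which = 1)
fit_biexp(decay)
#>     v_f   v_s     D_f      D_s degenerate converged
#> 1 0.633 0.367 0.00160 0.000120 FALSE      TRUE
```

The ROI-mean FA of 0.368 and MD of 0.62 µm²/ms are what the native
preset encodes: a strongly anisotropic, slowly diffusing medium. The
bi-exponential fit splits this voxel's decay along the fibre axis into a
fast fraction (v_f ≈ 0.63 at D_f ≈ 1.6 µm²/ms) and a slow compartment
two orders of magnitude less mobile. With the protocol's effective
diffusion time,

```r
tau <- effective_diffusion_time(3.55, 8.52)   # 7.3367 ms
rms_displacement(1.3e-3, tau)                 # 7.56 um
rms_displacement(0.17e-3, tau)                # 2.73 um
```

the fast and slow rates translate into probing length scales of roughly
8 µm and 3 µm — cell-scale and collagen-fibre-scale structure.

The full study design (three tissue groups × three samples × four
slices, n = 12 ROIs per group, all models, ANOVA + Tukey) runs with

```r
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
report$comparisons   # one-way ANOVA per index
autoplot(report)     # column plots by group
```

## Documentation

`vignettes/arterial-dmri-methods.Rmd` describes the signal models and
their assumptions, the directional-projection construction, the phantom
presets and what they do and do not emulate, the numerical choices, and
known limitations.
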