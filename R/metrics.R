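#' Fractional anisotropy and mean diffusivity
#'
#' `MD = (l1 + l2 + l3)/3` and
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||` (standard tensor FA,
#' scale-invariant, in \[0, 1\]).
#'
#' @param eigenvalues length-3 non-negative vector, or an n x 3 matrix.
#' @return A tibble with columns `FA` and `MD`; FA is `NA` for an all-zero
#'   tensor.
#' @export
fa_md <- function(eigenvalues) {
  lam <- matrix(eigenvalues, ncol = 3)
  if (any(lam < 0)) stop_input("eigenvalues must be non-negative")
  md <- rowMeans(lam)
  dev2 <- rowSums((lam - md)^2)
  nrm2 <- rowSums(lam^2)
  fa <- ifelse(nrm2 > 0, sqrt(1.5 * dev2 / nrm2), NA_real_)
  tibble::tibble(FA = fa, MD = md)
}

#' Westin geometric shape measures
#'
#' Sum-normalised barycentric decomposition of a tensor ellipsoid into
#' linear, planar and spherical components:
#' `C_L = (l1 - l2)/sum`, `C_P = 2 (l2 - l3)/sum`, `C_S = 3 l3/sum`,
#' so that `C_L + C_P + C_S = 1` and each lies in \[0, 1\].
#'
#' @param eigenvalues length-3 vector sorted descending (`l1 >= l2 >= l3 >=
#'   0`, positive sum), or an n x 3 matrix of such rows.
#' @return A tibble with columns `C_L`, `C_P`, `C_S`.
#' @export
westin_shapes <- function(eigenvalues) {
  lam <- matrix(eigenvalues, ncol = 3)
  if (any(lam < 0)) stop_input("eigenvalues must be non-negative")
  if (any(lam[, 1] < lam[, 2] | lam[, 2] < lam[, 3])) {
    stop_input("eigenvalues must be sorted descending")
  }
  s <- rowSums(lam)
  if (any(s <= 0)) stop_input("zero-trace tensor has no defined shape")
  tibble::tibble(
    C_L = (lam[, 1] - lam[, 2]) / s,
    C_P = 2 * (lam[, 2] - lam[, 3]) / s,
    C_S = 3 * lam[, 3] / s
  )
}

#' Bi-exponential summary diffusivity and kurtosis
#'
#' `D_biexp = v_f D_f + v_s D_s` and
#' `K_biexp = 3 v_f v_s (D_f - D_s)^2 / D_biexp^2`.
#'
#' @param fit a one-row tibble from [fit_biexp()] (or any list with fields
#'   `v_f`, `v_s`, `D_f`, `D_s`).
#' @return A one-row tibble with `D_biexp` (mm^2/s) and `K_biexp`.
#' @export
biexp_summary <- function(fit) {
  d <- fit$v_f * fit$D_f + fit$v_s * fit$D_s
  if (any(d == 0)) stop_input("D_biexp is zero: kurtosis undefined")
  k <- 3 * fit$v_f * fit$v_s * (fit$D_f - fit$D_s)^2 / d^2
  tibble::tibble(D_biexp = d, K_biexp = k)
}

#' Effective diffusion time
#'
#' `tau = Delta - delta/3` for a pulsed-gradient experiment with gradient
#' duration `delta` and separation `Delta` (both in ms).
#'
#' @param delta_small gradient pulse duration delta (ms), positive.
#' @param delta_big gradient separation Delta (ms), greater than `delta`.
#' @return Effective diffusion time in ms.
#' @export
effective_diffusion_time <- function(delta_small, delta_big) {
  if (any(delta_small <= 0) || any(delta_small >= delta_big)) {
    stop_input("timings must satisfy 0 < delta < Delta")
  }
  delta_big - delta_small / 3
}

#' Root-mean-square displacement scale
#'
#' `r = sqrt(6 D tau)` in micrometres, for a diffusivity in mm^2/s and an
#' effective diffusion time in ms.
#'
#' @param D diffusivity (mm^2/s), non-negative.
#' @param tau effective diffusion time (ms), positive.
#' @return Displacement scale in micrometres.
#' @export
rms_displacement <- function(D, tau) {
  if (any(D < 0)) stop_input("diffusivity must be non-negative")
  if (any(tau <= 0)) stop_input("diffusion time must be positive")
  sqrt(6 * D * tau * 1e-3) * 1e3   # mm^2/s * ms -> mm^2, then mm -> um
}
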