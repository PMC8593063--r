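#' Fit the mono-exponential (apparent diffusivity) model
#'
#' `ln S(b)/S(0) ~ -b D_app`. A log-linear least-squares slope provides the
#' initial estimate, refined by box-constrained non-linear least squares on
#' the signal scale with `D_app >= 0`.
#'
#' @param decay a [directional_decay()] (columns `b`, `sfrac`).
#' @param refine refine the log-linear slope by constrained NLLS.
#' @return A one-row tibble with `D_app` (mm^2/s) and `converged`.
#' @export
fit_monoexp <- function(decay, refine = TRUE) {
  use <- decay$sfrac > 0
  b <- decay$b[use]
  y <- decay$sfrac[use]
  if (length(unique(b)) < 2) {
    stop_input("mono-exponential fit needs >= 2 usable b-values")
  }
  d0 <- max(-sum(b * log(y)) / sum(b^2), 0)  # through-origin log slope
  d <- d0
  conv <- TRUE
  if (refine) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(D = d0),
        fn = function(p) y - exp(-b * p[1]),
        lower = 0,
        control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                             maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) conv <- FALSE else d <- unname(coef(fit))
  }
  tibble::tibble(D_app = d, converged = conv)
}

#' Fit the stretched-exponential model
#'
#' `S(b)/S(0) = exp(-(b^alpha) D_st)` with the heterogeneity index
#' `alpha` bounded in \[0.1, 1\]. The fit is initialised from the
#' mono-exponential solution (`alpha = 1`, `D_st = D_app`) and refined by
#' box-constrained non-linear least squares.
#'
#' @param decay a [directional_decay()].
#' @return A one-row tibble with `D_st`, `alpha` and `converged`.
#' @export
fit_stretched <- function(decay) {
  if (length(unique(decay$b)) < 3) {
    stop_input("stretched-exponential fit needs >= 3 distinct b-values")
  }
  d0 <- fit_monoexp(decay, refine = FALSE)$D_app
  b <- decay$b
  y <- decay$sfrac
  fit <- tryCatch(
    minpack.lm::nls.lm(
      # alpha starts a hair inside the box: exactly on the bound the
      # Levenberg-Marquardt step cannot move it off
      par = c(D = max(d0, 1e-12), alpha = 1 - 1e-6),
      fn = function(p) y - exp(-(b^p[2]) * p[1]),
      lower = c(1e-12, 0.1), upper = c(Inf, 1),
      control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(D_st = NA_real_, alpha = NA_real_,
                          converged = FALSE))
  }
  p <- coef(fit)
  tibble::tibble(D_st = unname(p[1]), alpha = unname(p[2]), converged = TRUE)
}

#' Fit the 1-D diffusion kurtosis model
#'
#' `ln S(b)/S(0) ~ -b D_app + (1/6) b^2 D_app^2 K_app`, restricted to
#' `b <= bmax`. A quadratic log-linear fit provides the initial estimate,
#' refined by box-constrained non-linear least squares with `D_app > 0`
#' and `K_app >= 0`.
#'
#' @param decay a [directional_decay()].
#' @param bmax maximum b-value used (default 2400 s/mm^2).
#' @return A one-row tibble with `D_app`, `K_app` and `converged`.
#' @export
fit_kurtosis_1d <- function(decay, bmax = 2400) {
  keep <- decay$b <= bmax & decay$sfrac > 0
  b <- decay$b[keep]
  y <- decay$sfrac[keep]
  if (length(unique(b)) < 3) {
    stop_input("kurtosis fit needs >= 3 distinct b-values at b <= bmax")
  }
  co <- coef(lm(log(y) ~ 0 + b + I(b^2)))
  d0 <- max(-co[1], 1e-12)
  k0 <- max(6 * co[2] / d0^2, 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(D = d0, K = k0),
      fn = function(p) y - exp(-b * p[1] + (b^2) * p[1]^2 * p[2] / 6),
      lower = c(1e-12, 0),
      control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(D_app = NA_real_, K_app = NA_real_,
                          converged = FALSE))
  }
  p <- coef(fit)
  tibble::tibble(D_app = unname(p[1]), K_app = unname(p[2]), converged = TRUE)
}

#' Fit the bi-exponential (two-compartment) model
#'
#' `S(b)/S(0) = v_f exp(-D_f b) + v_s exp(-D_s b)` with `v_f + v_s = 1` and
#' `D_f >= D_s >= 0`. Initial estimates come from segmented
#' mono-exponential fits: the fast diffusivity from the low-b slope
#' (`b <= b_low`), the slow diffusivity and the slow fraction from the
#' high-b log-linear line (`b >= b_high`), with
#' `v_f = 1 - exp(intercept)` clipped to \[0.05, 0.95\]. The refinement is
#' box-constrained non-linear least squares over
#' `(v_f, D_s, D_f - D_s)` so the ordering constraint is structural.
#' When the two diffusivities collapse (difference below 1e-6 mm^2/s) or
#' the fast fraction reaches 1, the slow compartment is unidentifiable:
#' the fit returns `v_f = 1`, `D_s = D_f` and sets `degenerate`.
#'
#' @param decay a [directional_decay()] spanning both segments.
#' @param b_low upper b of the fast segment (default 900 s/mm^2).
#' @param b_high lower b of the slow segment (default 1800 s/mm^2).
#' @return A one-row tibble with `v_f`, `v_s`, `D_f`, `D_s`, `degenerate`
#'   and `converged`.
#' @export
fit_biexp <- function(decay, b_low = 900, b_high = 1800) {
  lo <- decay$b <= b_low
  hi <- decay$b >= b_high
  if (sum(lo) < 2 || sum(hi) < 2) {
    stop_input("bi-exponential fit needs >= 2 points at b <= b_low and >= 2 at b >= b_high")
  }
  b <- decay$b
  y <- decay$sfrac
  df0 <- fit_monoexp(decay[lo, ], refine = FALSE)$D_app
  hi_fit <- coef(lm(log(y[hi]) ~ b[hi]))
  ds0 <- max(-hi_fit[2], 0)
  vf0 <- min(max(1 - exp(hi_fit[1]), 0.05), 0.95)
  dd0 <- max(df0 - ds0, 1e-6)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(vf = vf0, Ds = ds0, dd = dd0),
      fn = function(p) {
        y - (p[1] * exp(-(p[2] + p[3]) * b) + (1 - p[1]) * exp(-p[2] * b))
      },
      lower = c(0, 0, 0), upper = c(1, Inf, Inf),
      control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(v_f = NA_real_, v_s = NA_real_, D_f = NA_real_,
                          D_s = NA_real_, degenerate = NA, converged = FALSE))
  }
  p <- coef(fit)
  v_f <- unname(p[1])
  d_s <- unname(p[2])
  d_f <- d_s + unname(p[3])
  degenerate <- (d_f - d_s) < 1e-6 || v_f > 1 - 1e-9
  if (degenerate) {
    # slow compartment unidentifiable: collapse to a single compartment
    d_single <- if (v_f > 1 - 1e-9) d_f else v_f * d_f + (1 - v_f) * d_s
    v_f <- 1
    d_f <- d_single
    d_s <- d_single
  }
  tibble::tibble(v_f = v_f, v_s = 1 - v_f, D_f = d_f, D_s = d_s,
                 degenerate = degenerate, converged = TRUE)
}
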