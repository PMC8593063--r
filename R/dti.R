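#' Fit the diffusion tensor model voxel-wise
#'
#' Log-linear least squares on `ln S = ln S0 - b g' D g` over all
#' measurements with `b <= bmax`, optionally refined per voxel by
#' box-constrained non-linear least squares on the signal scale
#' (Levenberg-Marquardt with non-negative diagonal tensor elements and
#' positive S0). The tensor is eigen-decomposed with eigenvalues sorted
#' descending; negative eigenvalues are clipped to zero and the voxel
#' flagged.
#'
#' @param volume a [dwi_volume()].
#' @param bmax maximum b-value used for the fit (s/mm^2). The high multi
#'   b-value protocol uses `bmax = 900`, the high angular resolution
#'   protocol `bmax = 800`.
#' @param mask optional logical 3-D array restricting the fit.
#' @param refine refine the log-linear solution with constrained NLLS
#'   (default TRUE).
#' @return A tibble of class `tensor_fit` with one row per fitted voxel:
#'   voxel indices `i`, `j`, `k`, `S0`, the six tensor elements `dxx` ..
#'   `dyz`, eigenvalues `l1 >= l2 >= l3` (clipped at 0), eigenvector
#'   components `v1x` .. `v3z`, and a `clipped` flag. The b-value cutoff is
#'   stored in attribute `fit_bmax`.
#' @export
fit_dti <- function(volume, bmax = 900, mask = NULL, refine = TRUE) {
  scheme <- volume$scheme
  use <- scheme$b <= bmax
  b <- scheme$b[use]
  g <- scheme_directions(scheme)[use, , drop = FALSE]
  if (sum(use) < 7) stop_input("need at least 7 measurements at b <= bmax")
  X <- cbind(1, -b * quadratic_design(g))
  if (qr(X)$rank < 7) {
    stop_input("gradient design is rank deficient: need >= 6 non-collinear directions")
  }
  dims <- dim(volume$signal)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  vox <- which(mask, arr.ind = TRUE)

  flat <- matrix(volume$signal, prod(dims[1:3]), dims[4])[, use, drop = FALSE]
  lin_idx <- vox[, 1] + (vox[, 2] - 1L) * dims[1] +
    (vox[, 3] - 1L) * dims[1] * dims[2]
  S <- flat[lin_idx, , drop = FALSE]

  # vectorised log-linear solve (non-positive signals floored for the log)
  Smin <- pmax(S, 1e-12)
  beta <- t(qr.solve(X, t(log(Smin))))

  rows <- vector("list", nrow(vox))
  for (r in seq_len(nrow(vox))) {
    par <- beta[r, ]
    s <- S[r, ]
    if (refine && all(s > 0)) {
      init <- par
      init[2:4] <- pmax(init[2:4], 0)   # keep start inside the box
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(lnS0 = init[1], d = init[2:7]),
          fn = function(p) {
            s - exp(p[1]) * exp(-b * as.vector(quadratic_design(g) %*% p[2:7]))
          },
          lower = c(-Inf, 0, 0, 0, -Inf, -Inf, -Inf),
          control = minpack.lm::nls.lm.control(
            ptol = 1e-10, ftol = 1e-10, maxiter = 500)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) par <- unname(coef(fit))
    }
    D <- tensor_from_elements(par[c(2, 3, 4, 5, 6, 7)])
    ed <- eigen(D, symmetric = TRUE)   # descending eigenvalues
    lam <- ed$values
    clipped <- any(lam < 0)
    lam <- pmax(lam, 0)
    V <- ed$vectors
    rows[[r]] <- c(
      S0 = exp(par[1]),
      dxx = D[1, 1], dyy = D[2, 2], dzz = D[3, 3],
      dxy = D[1, 2], dxz = D[1, 3], dyz = D[2, 3],
      l1 = lam[1], l2 = lam[2], l3 = lam[3],
      v1x = V[1, 1], v1y = V[2, 1], v1z = V[3, 1],
      v2x = V[1, 2], v2y = V[2, 2], v2z = V[3, 2],
      v3x = V[1, 3], v3y = V[2, 3], v3z = V[3, 3],
      clipped = as.numeric(clipped)
    )
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(i = vox[, 1], j = vox[, 2], k = vox[, 3]), out
  )
  out$clipped <- out$clipped > 0
  attr(out, "fit_bmax") <- bmax
  class(out) <- c("tensor_fit", class(out))
  out
}

# Eigenvector matrix (columns v1, v2, v3) from one tensor_fit row.
fit_eigenframe <- function(fit_row) {
  matrix(c(fit_row$v1x, fit_row$v1y, fit_row$v1z,
           fit_row$v2x, fit_row$v2y, fit_row$v2z,
           fit_row$v3x, fit_row$v3y, fit_row$v3z), 3, 3)
}

#' Extract the signal decay along a tensor eigenvector
#'
#' For each shell, the log-signal is fit as an even angular model in the
#' tensor eigenframe — the second-order (apparent tensor) terms plus
#' frame-aligned fourth-order terms — and evaluated at the chosen
#' eigenvector, giving one normalised sample `S(b)/S(0)` per shell along
#' that axis. S(0) is the average over all b0 measurements of the voxel.
#' The fourth-order terms capture the angular curvature that
#' multi-compartment signal adds on top of a single tensor; for
#' single-tensor data they vanish and the projection is exact. All
#' non-Gaussian 1-D models are fit to these directional decays so that
#' every model shares the mono-exponential (DTI) frame of reference.
#'
#' @param volume a [dwi_volume()].
#' @param tensor one row of a [fit_dti()] result (supplies the voxel indices
#'   and the eigenframe).
#' @param which eigenvector index: 1 (primary), 2 (secondary), 3 (tertiary).
#' @return A tibble of class `directional_decay` with columns `b` (strictly
#'   increasing) and `sfrac`; the direction and eigenvector index are stored
#'   as attributes `direction` and `source`.
#' @export
extract_directional_decay <- function(volume, tensor, which = 1) {
  stopifnot(which %in% 1:3)
  if (nrow(tensor) != 1) stop_input("`tensor` must be a single tensor_fit row")
  scheme <- volume$scheme
  s <- volume$signal[tensor$i, tensor$j, tensor$k, ]
  s0 <- mean(s[scheme$is_b0])
  if (!is.finite(s0) || s0 <= 0) stop_input("voxel has no usable b0 signal")
  shells <- sort(unique(scheme$b[!scheme$is_b0]))
  V <- fit_eigenframe(tensor)
  sfrac <- vapply(shells, function(bv) {
    sel <- scheme$b == bv
    if (sum(sel) < 6) {
      stop_input("each shell needs >= 6 directions for the directional projection")
    }
    # per-shell even angular model of the log-signal in the eigenframe:
    # quadratic terms plus frame-aligned fourth-order terms (the models all
    # share the tensor frame, so the quartic axes are taken along it)
    u <- scheme_directions(scheme)[sel, , drop = FALSE] %*% V
    X <- cbind(u^2, u^4)
    y <- log(pmax(s[sel], 1e-12) / s0)
    theta <- if (qr(X)$rank == 6) {
      qr.solve(X, y)
    } else {
      c(qr.solve(X[, 1:3, drop = FALSE], y), 0, 0, 0)
    }
    exp(theta[which] + theta[which + 3])   # value at the chosen eigenvector
  }, numeric(1))
  directional_decay(shells, sfrac, direction = V[, which], source = which)
}

#' Construct a directional decay curve
#'
#' @param b strictly increasing b-values (s/mm^2), excluding b = 0.
#' @param sfrac signal fractions S(b)/S(0), finite and in (0, 1.5].
#' @param direction unit 3-vector the decay was sampled along.
#' @param source eigenvector index (1, 2 or 3) or NA for ad-hoc directions.
#' @return A tibble of class `directional_decay`.
#' @export
directional_decay <- function(b, sfrac, direction = c(1, 0, 0), source = NA) {
  if (is.unsorted(b, strictly = TRUE)) {
    stop_input("b-values must be strictly increasing")
  }
  if (any(!is.finite(sfrac)) || any(sfrac <= 0) || any(sfrac > 1.5)) {
    stop_input("signal fractions must be finite and in (0, 1.5]")
  }
  out <- tibble::tibble(b = as.numeric(b), sfrac = as.numeric(sfrac))
  attr(out, "direction") <- direction / sqrt(sum(direction^2))
  attr(out, "source") <- source
  class(out) <- c("directional_decay", class(out))
  out
}
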