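# Fourth-order symmetric tensor bookkeeping: the 15 unique elements of W
# in lexicographic index order, with the multiplicity of each element in
# the full 81-term contraction n_i n_j n_k n_l W_ijkl.
w_index_table <- function() {
  idx <- t(utils::combn(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), 4))
  idx <- unique(t(apply(idx, 1, sort)))
  mult <- apply(idx, 1, function(r) {
    factorial(4) / prod(factorial(table(r)))
  })
  nm <- apply(idx, 1, function(r) paste0("w", paste(c("x", "y", "z")[r],
                                                    collapse = "")))
  list(idx = idx, mult = mult, names = nm)
}

# Design row(s) for the fourth-order form: W(n) as a linear form in the 15
# unique elements (multiplicities included).
quartic_design <- function(g) {
  g <- matrix(g, ncol = 3)
  tab <- w_index_table()
  out <- sapply(seq_len(nrow(tab$idx)), function(c_i) {
    r <- tab$idx[c_i, ]
    tab$mult[c_i] * g[, r[1]] * g[, r[2]] * g[, r[3]] * g[, r[4]]
  })
  matrix(out, nrow = nrow(g), dimnames = list(NULL, tab$names))
}

#' Fit the diffusion kurtosis tensor voxel-wise
#'
#' Weighted linear least squares of `ln S` on the six diffusion-tensor and
#' fifteen kurtosis-tensor design terms,
#' `ln S = ln S0 - b D(n) + (b^2/6) MD^2 W(n)`,
#' using all shells of the scheme (the high angular resolution protocol by
#' construction). The first pass is ordinary least squares; the second pass
#' re-weights by the squared predicted signal, the standard heteroscedasticity
#' correction for log-linearised fits.
#'
#' @param volume a [dwi_volume()].
#' @param mask optional logical 3-D array restricting the fit.
#' @param weighted apply the second, signal-weighted pass (default TRUE).
#' @return A tibble of class `dki_fit` with one row per voxel: indices,
#'   `S0`, tensor elements `dxx` .. `dyz`, `md`, and the 15 kurtosis tensor
#'   elements `wxxxx` .. `wzzzz` (dimensionless, index-permutation
#'   symmetric by construction).
#' @export
fit_dki_tensor <- function(volume, mask = NULL, weighted = TRUE) {
  scheme <- volume$scheme
  b <- scheme$b
  g <- scheme_directions(scheme)
  shells <- unique(b[b > 0])
  if (length(shells) < 2) stop_input("DKI needs at least 2 non-zero shells")
  X2 <- quadratic_design(g)
  X4 <- quartic_design(g)
  X <- cbind(1, -b * X2, (b^2 / 6) * X4)
  if (qr(X)$rank < ncol(X)) {
    stop_input("gradient design is rank deficient: need >= 15 non-collinear directions")
  }
  dims <- dim(volume$signal)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  vox <- which(mask, arr.ind = TRUE)
  flat <- matrix(volume$signal, prod(dims[1:3]), dims[4])
  lin_idx <- vox[, 1] + (vox[, 2] - 1L) * dims[1] +
    (vox[, 3] - 1L) * dims[1] * dims[2]
  S <- flat[lin_idx, , drop = FALSE]
  tab <- w_index_table()

  rows <- vector("list", nrow(vox))
  for (r in seq_len(nrow(vox))) {
    y <- log(pmax(S[r, ], 1e-12))
    beta <- qr.solve(X, y)
    if (weighted) {
      w <- exp(X %*% beta)^2
      xw <- X * as.vector(sqrt(w))
      beta <- qr.solve(xw, y * as.vector(sqrt(w)))
    }
    d_el <- beta[2:7]
    md <- mean(d_el[1:3])
    w_hat <- beta[8:22]                     # = MD^2 * W elements
    w_el <- if (md > 0) w_hat / md^2 else w_hat * NA_real_
    row <- c(S0 = exp(beta[1]),
             dxx = d_el[1], dyy = d_el[2], dzz = d_el[3],
             dxy = d_el[4], dxz = d_el[5], dyz = d_el[6],
             md = md, setNames(w_el, tab$names))
    rows[[r]] <- row
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(i = vox[, 1], j = vox[, 2], k = vox[, 3]), out
  )
  class(out) <- c("dki_fit", class(out))
  out
}

# Directional diffusivity D(n) from one dki_fit row.
dki_directional_d <- function(dki_row, n) {
  el <- c(dki_row$dxx, dki_row$dyy, dki_row$dzz,
          dki_row$dxy, dki_row$dxz, dki_row$dyz)
  as.vector(quadratic_design(n) %*% el)
}

#' Apparent kurtosis along a direction
#'
#' `K(n) = (MD^2 / D(n)^2) W(n)` with `D(n)` and `W(n)` the second- and
#' fourth-order forms of the fitted tensor pair contracted with the unit
#' direction `n`. Invariant under `n -> -n`.
#'
#' @param dki one row of a [fit_dki_tensor()] result.
#' @param n unit 3-vector or matrix of row vectors.
#' @return Apparent kurtosis value(s).
#' @export
apparent_kurtosis <- function(dki, n) {
  if (nrow(dki) != 1) stop_input("`dki` must be a single dki_fit row")
  n <- matrix(n, ncol = 3)
  dn <- dki_directional_d(dki, n)
  if (any(dn <= 0)) {
    stop_input("directional diffusivity is not positive: kurtosis undefined")
  }
  tab <- w_index_table()
  w_el <- as.numeric(dki[1, tab$names])
  wn <- as.vector(quartic_design(n) %*% w_el)
  (dki$md^2 / dn^2) * wn
}

# Unit vectors forming a ring perpendicular to axis v1 (for radial kurtosis).
ring_directions <- function(v1, n = 36) {
  ref <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * v1) * v1
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v1[2] * e1[3] - v1[3] * e1[2],
          v1[3] * e1[1] - v1[1] * e1[3],
          v1[1] * e1[2] - v1[2] * e1[1])
  phi <- seq(0, pi, length.out = n + 1)[-(n + 1)]
  t(vapply(phi, function(p) cos(p) * e1 + sin(p) * e2, numeric(3)))
}

#' Scalar kurtosis indices from a fitted kurtosis tensor
#'
#' Mean kurtosis (MK) is the average of the apparent kurtosis over a seeded
#' set of approximately uniform directions; axial kurtosis (AK) the value
#' along the principal eigenvector; radial kurtosis (RK) the average over a
#' ring of directions perpendicular to it; kurtosis anisotropy (KA) the
#' standard deviation of the apparent kurtosis over the sample directions;
#' and tortuosity (TORT) the ratio of the axial to the mean radial
#' diffusivity, `l1 / ((l2 + l3)/2)`.
#'
#' @param dki one row of a [fit_dki_tensor()] result.
#' @param n_dirs number of sample directions for MK/KA (default 100).
#' @param ring_n number of ring directions for RK (default 36).
#' @param seed seed of the direction sample.
#' @return A one-row tibble with `KA`, `MK`, `AK`, `RK`, `TORT`.
#' @export
dki_indices <- function(dki, n_dirs = 100, ring_n = 36, seed = 42L) {
  if (nrow(dki) != 1) stop_input("`dki` must be a single dki_fit row")
  el <- tensor_from_elements(c(dki$dxx, dki$dyy, dki$dzz,
                               dki$dxy, dki$dxz, dki$dyz))
  ed <- eigen(el, symmetric = TRUE)
  lam <- ed$values
  v1 <- ed$vectors[, 1]
  dirs <- generate_directions(n_dirs, seed = seed)
  kn <- apparent_kurtosis(dki, dirs)
  mk <- mean(kn)
  ka <- sd(kn)
  ak <- apparent_kurtosis(dki, v1)
  rk <- mean(apparent_kurtosis(dki, ring_directions(v1, ring_n)))
  tort <- if ((lam[2] + lam[3]) > 0) lam[1] / ((lam[2] + lam[3]) / 2) else {
    NA_real_
  }
  tibble::tibble(KA = ka, MK = mk, AK = ak, RK = rk, TORT = tort)
}
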