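#' Marchenko-Pastur PCA noise estimation and denoising
#'
#' Exploits the redundancy of multi-shell dMRI data: for each voxel, the
#' local patch (spatial window x measurements) is eigen-decomposed and the
#' noise level identified as the largest trailing set of eigenvalues whose
#' spread is compatible with the Marchenko-Pastur law for pure-noise
#' matrices. The signal is reconstructed from the remaining principal
#' components and the per-voxel noise standard deviation is returned as a
#' map.
#'
#' @param volume a [dwi_volume()].
#' @param patch_radius spatial half-width of the cubic patch (default 2,
#'   i.e. 5 x 5 x 5 voxels, truncated at the volume edges).
#' @return A list of class `noise_estimate` with `sigma_map` (3-D array) and
#'   `denoised` (4-D array, same shape as the input signal, clipped at 0).
#' @export
mppca_denoise <- function(volume, patch_radius = 2L) {
  dims <- dim(volume$signal)
  m <- dims[4]
  if (m < 2) stop_input("need at least 2 measurements to estimate noise")
  if (patch_radius < 1) stop_input("`patch_radius` must be >= 1")

  flat <- matrix(volume$signal, prod(dims[1:3]), m)
  sigma_map <- array(NA_real_, dims[1:3])
  denoised <- array(0, dims)

  idx3 <- function(i, j, k) i + (j - 1L) * dims[1] + (k - 1L) * dims[1] * dims[2]
  r <- as.integer(patch_radius)

  for (k in seq_len(dims[3])) {
    kk <- max(1L, k - r):min(dims[3], k + r)
    for (j in seq_len(dims[2])) {
      jj <- max(1L, j - r):min(dims[2], j + r)
      for (i in seq_len(dims[1])) {
        ii <- max(1L, i - r):min(dims[1], i + r)
        vox <- as.vector(outer(outer(ii, (jj - 1L) * dims[1], "+"),
                               (kk - 1L) * dims[1] * dims[2], "+"))
        X <- flat[vox, , drop = FALSE]
        centre_row <- match(idx3(i, j, k), vox)
        res <- mp_patch(X, centre_row)
        sigma_map[i, j, k] <- res$sigma
        denoised[i, j, k, ] <- res$centre
      }
    }
  }
  denoised[denoised < 0] <- 0
  structure(list(sigma_map = sigma_map, denoised = denoised),
            class = "noise_estimate")
}

# MP criterion on one patch matrix X (patch voxels x measurements).
# Returns the noise sigma and the denoised centre-voxel row.
mp_patch <- function(X, centre_row) {
  n <- nrow(X)
  m <- ncol(X)
  transposed <- m > n
  A <- if (transposed) t(X) else X   # rows >= cols
  nn <- nrow(A)
  mm <- ncol(A)
  sv <- svd(A)
  vals <- sv$d^2 / nn                 # eigenvalues of A'A / nn, descending
  p_sel <- 0L
  sigma2 <- mean(vals)
  for (p in 0:(mm - 1L)) {
    tail_vals <- vals[(p + 1L):mm]
    s2 <- mean(tail_vals)
    gamma <- (mm - p) / nn
    spread <- tail_vals[1] - tail_vals[length(tail_vals)]
    if (spread <= 4 * s2 * sqrt(gamma)) {
      p_sel <- p
      sigma2 <- s2
      break
    }
    p_sel <- p + 1L
    sigma2 <- 0
  }
  if (p_sel >= mm) {
    centre <- X[centre_row, ]
    return(list(sigma = sqrt(max(sigma2, 0)), centre = centre))
  }
  if (p_sel == 0L) {
    return(list(sigma = sqrt(max(sigma2, 0)), centre = rep(0, m)))
  }
  keep <- seq_len(p_sel)
  A_hat <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  X_hat <- if (transposed) t(A_hat) else A_hat
  list(sigma = sqrt(max(sigma2, 0)), centre = X_hat[centre_row, ])
}

#' Rician bias correction of magnitude data
#'
#' Wherever the denoised signal is below `snr_threshold` times the local
#' noise level, the denoised magnitude is treated as a proxy for the Rician
#' expectation value and the underlying amplitude recovered by
#' method-of-moments inversion of the second moment,
#' `s_hat = sqrt(max(m^2 - 2 sigma^2, 0))`. Voxels at or above the
#' threshold pass through unchanged.
#'
#' @param volume a [dwi_volume()] (typically already denoised).
#' @param noise a `noise_estimate` from [mppca_denoise()].
#' @param snr_threshold SNR below which the correction is applied
#'   (default 3).
#' @return A [dwi_volume()] with bias-corrected non-negative signal.
#' @export
rician_bias_correct <- function(volume, noise, snr_threshold = 3) {
  dims <- dim(volume$signal)
  if (!all(dim(noise$denoised) == dims) ||
      !all(dim(noise$sigma_map) == dims[1:3])) {
    stop_input("noise estimate shape does not match the volume")
  }
  sigma4 <- array(noise$sigma_map, dims)  # recycle sigma over measurements
  m <- noise$denoised
  low <- sigma4 > 0 & m / sigma4 < snr_threshold
  out <- volume$signal
  out[low] <- sqrt(pmax(m[low]^2 - 2 * sigma4[low]^2, 0))
  dwi_volume(out, volume$scheme, volume$voxel_size)
}

#' Background noise floor
#'
#' The noise floor is the standard deviation of the magnitude signal over a
#' signal-free background region, pooled across all b0 measurements.
#'
#' @param volume a [dwi_volume()].
#' @param background_mask logical 3-D array marking background voxels.
#' @return Noise floor in signal units.
#' @export
noise_floor <- function(volume, background_mask) {
  if (!any(background_mask)) stop_input("background mask is empty")
  b0_idx <- which(volume$scheme$is_b0)
  if (length(b0_idx) == 0) stop_input("scheme contains no b0 measurements")
  vals <- vapply(b0_idx, function(t) volume$signal[, , , t][background_mask],
                 numeric(sum(background_mask)))
  sd(as.vector(vals))
}
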