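#' DWI volume objects
#'
#' A `dwi_volume` bundles a 4-D magnitude signal array (x, y, z,
#' measurement) with its [gradient_scheme()] and the voxel size in mm.
#'
#' @param signal 4-D non-negative numeric array; the 4th axis must match the
#'   scheme length.
#' @param scheme a [gradient_scheme()].
#' @param voxel_size numeric length-3 vector (mm).
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(1, 1, 1)) {
  if (length(dim(signal)) != 4) stop_input("`signal` must be a 4-D array")
  if (dim(signal)[4] != nrow(scheme)) {
    stop_input("4th axis of `signal` must match the gradient scheme length")
  }
  if (any(signal < 0)) stop_input("magnitude signal must be non-negative")
  structure(
    list(signal = signal, scheme = scheme,
         voxel_size = as.numeric(voxel_size)),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume>  %d x %d x %d voxels, %d measurements (%s)\n",
              d[1], d[2], d[3], d[4], attr(x$scheme, "label")))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Read and write diffusion-weighted volumes (NIfTI + FSL bval/bvec)
#'
#' `read_dwi()` loads a 4-D NIfTI image together with FSL-dialect gradient
#' tables: `bval` is a single whitespace-separated row of b-values and
#' `bvec` holds three rows with the x, y and z direction components.
#' Directions at b = 0 may be zero vectors and are flagged `is_b0`.
#' `write_dwi()` is the inverse; the round trip reproduces the signal array
#' bit-exactly and the gradient table to within text precision.
#'
#' @param image_path path to a 4-D NIfTI file.
#' @param bval_path,bvec_path paths to the FSL gradient-table text files.
#' @param delta_small,delta_big pulse timings (ms) to attach to the scheme
#'   (not stored in the FSL files).
#' @param label protocol label for the scheme.
#' @return `read_dwi()` returns a [dwi_volume()]; `write_dwi()` returns the
#'   paths invisibly.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path,
                     delta_small = 3.55, delta_big = 8.52, label = "file") {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # plain array, no NIfTI attributes
  if (length(dim(arr)) != 4) stop_input("image must be 4-D")
  b <- scan(bval_path, quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3) {
    stop_input("bvec file must contain exactly 3 rows (x, y, z components)")
  }
  g <- t(vapply(bvec_lines, function(l) scan(text = l, quiet = TRUE),
                numeric(length(b))))
  if (length(b) != dim(arr)[4]) {
    stop_input("gradient table length does not match the image 4th axis")
  }
  g <- t(g)
  # renormalise non-b0 rows written with finite precision
  nrm <- sqrt(rowSums(g^2))
  dw <- b > 0 & nrm > 0
  g[dw, ] <- g[dw, , drop = FALSE] / nrm[dw]
  g[b == 0, ] <- 0
  scheme <- gradient_scheme(b, g, delta_small = delta_small,
                            delta_big = delta_big, label = label)
  vx <- RNifti::pixdim(img)[1:3]
  if (length(vx) < 3 || any(!is.finite(vx)) || all(vx == 0)) vx <- c(1, 1, 1)
  dwi_volume(arr, scheme, voxel_size = vx)
}

#' @rdname read_dwi
#' @param volume a [dwi_volume()].
#' @export
write_dwi <- function(volume, image_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(volume$signal)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  RNifti::writeNifti(img, image_path, datatype = "double")
  writeLines(paste(format(volume$scheme$b, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  g <- scheme_directions(volume$scheme)
  writeLines(apply(t(g), 1, function(row) {
    paste(formatC(row, format = "g", digits = 15), collapse = " ")
  }), bvec_path)
  invisible(c(image_path, bval_path, bvec_path))
}

write_map_nifti <- function(map, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- c(voxel_size[seq_along(dim(map))], 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
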