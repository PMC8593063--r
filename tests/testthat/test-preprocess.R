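test_that("MP-PCA recovers the noise level of pure-noise volumes", {
  scheme <- tiny_scheme(shells = c(500, 1500), n_dirs = 25, n_b0 = 10)
  stopifnot(nrow(scheme) == 60)
  set.seed(21)
  # Gaussian noise sigma = 10 on a large offset keeps magnitudes positive
  # while leaving the noise statistics untouched
  arr <- array(1000 + rnorm(8 * 8 * 8 * 60, sd = 10), c(8, 8, 8, 60))
  est <- mppca_denoise(dwi_volume(arr, scheme), patch_radius = 2)
  expect_equal(median(est$sigma_map), 10, tolerance = 0.05)
  # sigma map is spatially flat on stationary noise
  expect_lt(sd(est$sigma_map) / mean(est$sigma_map), 0.10)
})

test_that("noise-free rank-1 data passes through MP-PCA unchanged", {
  scheme <- tiny_scheme(n_dirs = 4, n_b0 = 2)
  decay <- exp(-scheme$b * 1e-3)
  arr <- array(rep(100 * decay, each = 64), c(4, 4, 4, nrow(scheme)))
  est <- mppca_denoise(dwi_volume(arr, scheme), patch_radius = 1)
  expect_lt(max(abs(est$denoised - arr)), 1e-6 * max(arr))
  expect_lt(max(est$sigma_map), 1e-8)
})

test_that("denoising reduces mean squared error on a noisy phantom", {
  scheme <- tiny_scheme(n_dirs = 8, n_b0 = 5)
  spec <- phantom_spec("native", grid_shape = c(14, 14, 3),
                       ring_inner = 2.5, ring_outer = 5.5, snr_b0 = 20,
                       seed = 8)
  noisy <- make_phantom(spec, scheme)
  spec0 <- spec
  spec0$snr_b0 <- Inf
  clean <- make_phantom(spec0, scheme)
  est <- mppca_denoise(noisy$volume, patch_radius = 1)
  mse_before <- mean((noisy$volume$signal - clean$volume$signal)^2)
  mse_after <- mean((est$denoised - clean$volume$signal)^2)
  expect_lt(mse_after, mse_before)
})

test_that("Rician bias correction inverts the Rayleigh floor and spares high SNR", {
  scheme <- tiny_scheme(shells = 1000, n_dirs = 6, n_b0 = 1)
  n_meas <- nrow(scheme)
  dims <- c(2, 1, 1, n_meas)
  # voxel 1: zero true signal observed at the Rayleigh mean, sigma = 1;
  # voxel 2: SNR 10, should pass through untouched
  m <- array(0, dims)
  m[1, 1, 1, ] <- sqrt(pi / 2)          # Rayleigh expectation for sigma = 1
  m[2, 1, 1, ] <- 10
  noise <- structure(list(
    sigma_map = array(1, dims[1:3]),
    denoised = m
  ), class = "noise_estimate")
  vol <- dwi_volume(m, scheme)
  out <- rician_bias_correct(vol, noise, snr_threshold = 3)
  # sqrt(max(pi/2 - 2, 0)) clips to zero
  expect_equal(out$signal[1, 1, 1, ], rep(0, n_meas))
  expect_equal(out$signal[2, 1, 1, ], rep(10, n_meas))
  # correction only ever lowers the magnitude
  expect_true(all(out$signal <= vol$signal + 1e-12))
  expect_true(all(out$signal >= 0))
})

test_that("bias-corrected background mean drops on a noisy phantom", {
  scheme <- tiny_scheme(shells = c(500, 2500), n_dirs = 6, n_b0 = 4)
  spec <- phantom_spec("native", grid_shape = c(14, 14, 2),
                       ring_inner = 2.5, ring_outer = 5, snr_b0 = 10,
                       seed = 14)
  ph <- make_phantom(spec, scheme)
  est <- mppca_denoise(ph$volume, patch_radius = 1)
  corrected <- rician_bias_correct(
    dwi_volume(est$denoised, scheme, ph$volume$voxel_size), est
  )
  bg4 <- array(ph$background_mask, dim(ph$volume$signal))
  expect_lt(mean(corrected$signal[bg4]), mean(ph$volume$signal[bg4]))
  expect_true(all(corrected$signal >= 0))
})

test_that("noise floor is the background standard deviation over b0 data", {
  scheme <- tiny_scheme(shells = 1000, n_dirs = 6, n_b0 = 4)
  dims <- c(18, 18, 2, nrow(scheme))
  mask <- array(TRUE, dims[1:3])

  vol_const <- dwi_volume(array(7, dims), scheme)
  expect_equal(noise_floor(vol_const, mask), 0)

  # Rayleigh background, sigma = 5: SD = 5 sqrt((4 - pi)/2)
  set.seed(30)
  ray <- sqrt(rnorm(prod(dims), sd = 5)^2 + rnorm(prod(dims), sd = 5)^2)
  vol_ray <- dwi_volume(array(ray, dims), scheme)
  expect_equal(noise_floor(vol_ray, mask), 5 * sqrt((4 - pi) / 2),
               tolerance = 0.03)

  # invariant under a constant offset
  vol_shift <- dwi_volume(array(ray + 100, dims), scheme)
  expect_equal(noise_floor(vol_shift, mask), noise_floor(vol_ray, mask),
               tolerance = 1e-9)

  expect_error(noise_floor(vol_const, array(FALSE, dims[1:3])), "empty")
})
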