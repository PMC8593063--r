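test_that("forward signal matches closed forms", {
  iso <- compartment_params(1, rep(1e-3, 3), rep(0.99e-3, 3))
  expect_equal(forward_signal(iso, diag(3), 0, c(1, 0, 0)), 1)
  expect_equal(forward_signal(iso, diag(3), 1000, c(1, 0, 0)), exp(-1),
               tolerance = 1e-12)

  native_iso <- compartment_params(0.5, rep(1.3e-3, 3), rep(0.17e-3, 3))
  for (g in list(c(0, 1, 0), c(1, 0, 0), c(1, 1, 1) / sqrt(3))) {
    expect_equal(forward_signal(native_iso, diag(3), 1000, g),
                 0.5 * exp(-1.3) + 0.5 * exp(-0.17), tolerance = 1e-12)
  }
  expect_error(forward_signal(iso, diag(3), 1000, c(2, 0, 0)), "unit norm")
})

test_that("compartment parameters enforce fraction and ordering invariants", {
  p <- compartment_params(0.3, c(2, 1, 1) * 1e-3, c(0.3, 0.2, 0.1) * 1e-3)
  expect_equal(p$v_f + p$v_s, 1, tolerance = 1e-12)
  expect_error(compartment_params(1.2, rep(1e-3, 3), rep(1e-4, 3)))
  expect_error(
    compartment_params(0.5, rep(0.1e-3, 3), rep(1e-3, 3)),
    "fast"
  )
  for (ph in c("native", "collagenase", "decellularized")) {
    pp <- phenotype_preset(ph)
    expect_equal(pp$v_f + pp$v_s, 1, tolerance = 1e-12)
    expect_gte(mean(pp$D_f_eigs), mean(pp$D_s_eigs))
  }
})

test_that("noise-free phantom equals the forward model with zero background", {
  scheme <- tiny_scheme(n_dirs = 6, n_b0 = 2)
  spec <- phantom_spec("native", grid_shape = c(12, 12, 2),
                       ring_inner = 2, ring_outer = 4, snr_b0 = Inf,
                       seed = 1)
  ph <- make_phantom(spec, scheme)
  expect_true(all(ph$volume$signal[array(ph$background_mask,
                                         dim(ph$volume$signal))] == 0))
  # a media voxel reproduces forward_signal exactly
  v <- ph$truth[1, ]
  R <- arterydmri:::ring_rotation(v$theta)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  expected <- spec$s0 * forward_signal(spec$compartments, R, scheme$b, g)
  expect_equal(ph$volume$signal[v$i, v$j, v$k, ], expected,
               tolerance = 1e-12)
  # diffusion-weighted signal never exceeds the b0 signal
  b0 <- ph$volume$signal[, , , which(scheme$is_b0)[1]]
  for (t in which(!scheme$is_b0)[1:5]) {
    expect_true(all(ph$volume$signal[, , , t] <= b0 + 1e-9))
  }
})

test_that("phantom noise is seeded and Rician", {
  scheme <- tiny_scheme(shells = c(500, 1500), n_dirs = 6, n_b0 = 30)
  spec <- phantom_spec("native", grid_shape = c(20, 20, 2),
                       ring_inner = 2, ring_outer = 4, snr_b0 = 20,
                       seed = 11)
  ph1 <- make_phantom(spec, scheme)
  ph2 <- make_phantom(spec, scheme)
  expect_identical(ph1$volume$signal, ph2$volume$signal)

  # background magnitude is Rayleigh: mean sigma * sqrt(pi/2)
  sigma <- spec$s0 / spec$snr_b0
  bg <- ph1$volume$signal[array(ph1$background_mask,
                                dim(ph1$volume$signal))]
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("invalid phantom geometry is rejected", {
  scheme <- tiny_scheme(shells = 1000, n_dirs = 6, n_b0 = 1)
  expect_error(make_phantom(
    phantom_spec(grid_shape = c(8, 8, 2), ring_inner = 2, ring_outer = 6),
    scheme
  ), "fit")
  expect_error(phantom_spec(ring_inner = 5, ring_outer = 3), "inner")
  expect_error(phantom_spec(snr_b0 = -2), "snr")
})

test_that("phantom export writes image, tables, masks and sidecar", {
  scheme <- tiny_scheme(shells = 1000, n_dirs = 6, n_b0 = 2)
  spec <- phantom_spec("native", grid_shape = c(10, 10, 1),
                       ring_inner = 2, ring_outer = 4, snr_b0 = Inf)
  ph <- make_phantom(spec, scheme)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir, name = "ph")
  expect_true(all(file.exists(file.path(dir, c(
    "ph.nii.gz", "ph.bval", "ph.bvec",
    "ph_media_mask.nii.gz", "ph_background_mask.nii.gz", "ph_spec.yaml"
  )))))
  side <- yaml::read_yaml(file.path(dir, "ph_spec.yaml"))
  expect_equal(side$phenotype, "native")
  expect_equal(side$v_f, 0.5)
})
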