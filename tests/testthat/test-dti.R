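test_that("tensor fit recovers a known tensor exactly on noise-free data", {
  scheme <- tiny_scheme(n_dirs = 12, n_b0 = 4)
  eigs <- c(1.5, 0.9, 0.5) * 1e-3
  sig <- tensor_signal(scheme, eigs)
  vol <- one_voxel_volume(sig, scheme)
  tf <- fit_dti(vol, bmax = 900)
  expect_equal(attr(tf, "fit_bmax"), 900)
  expect_equal(c(tf$l1, tf$l2, tf$l3), eigs, tolerance = 1e-9)
  expect_equal(tf$S0, 100, tolerance = 1e-9)
  # eigenvectors orthonormal
  V <- arterydmri:::fit_eigenframe(tf[1, ])
  expect_lt(max(abs(t(V) %*% V - diag(3))), 1e-9)
})

test_that("tensor fit recovers a rotated anisotropic tensor", {
  scheme <- tiny_scheme(n_dirs = 12, n_b0 = 4)
  th <- 0.7
  R <- arterydmri:::ring_rotation(th)
  eigs <- c(1.8, 1.0, 0.4) * 1e-3
  vol <- one_voxel_volume(tensor_signal(scheme, eigs, R), scheme)
  tf <- fit_dti(vol, bmax = 900)
  expect_equal(c(tf$l1, tf$l2, tf$l3), eigs, tolerance = 1e-8)
  v1 <- c(tf$v1x, tf$v1y, tf$v1z)
  expect_equal(abs(sum(v1 * R[, 1])), 1, tolerance = 1e-8)
})

test_that("isotropic voxels give equal eigenvalues", {
  scheme <- tiny_scheme(n_dirs = 8, n_b0 = 2)
  vol <- one_voxel_volume(tensor_signal(scheme, rep(1e-3, 3)), scheme)
  tf <- fit_dti(vol, bmax = 900)
  expect_equal(tf$l1, tf$l2, tolerance = 1e-9)
  expect_equal(tf$l2, tf$l3, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
  # fewer than 7 usable measurements below bmax
  scheme <- tiny_scheme(shells = 3000, n_dirs = 12, n_b0 = 2)
  vol <- one_voxel_volume(tensor_signal(scheme, rep(1e-3, 3)), scheme)
  expect_error(fit_dti(vol, bmax = 900), "at least 7")

  # collinear directions: rank-deficient design
  g <- rbind(matrix(0, 3, 3), matrix(rep(c(1, 0, 0), 8), ncol = 3,
                                     byrow = TRUE))
  b <- c(rep(0, 3), rep(c(300, 600), 4))
  bad <- gradient_scheme(b, g, 3.55, 8.52)
  volb <- one_voxel_volume(rep(1, nrow(bad)), bad)
  expect_error(fit_dti(volb, bmax = 900), "rank deficient")
})

test_that("directional decay matches closed forms on single-tensor data", {
  scheme <- tiny_scheme(n_dirs = 12, n_b0 = 4)
  eigs <- c(1.5, 0.9, 0.5) * 1e-3
  vol <- one_voxel_volume(tensor_signal(scheme, eigs), scheme)
  tf <- fit_dti(vol, bmax = 900)
  for (w in 1:3) {
    dec <- extract_directional_decay(vol, tf[1, ], which = w)
    expect_equal(dec$b, hmb_shells)
    expect_equal(dec$sfrac, exp(-dec$b * eigs[w]), tolerance = 1e-6)
    expect_equal(attr(dec, "source"), w)
  }
})

test_that("directional decay is direction-independent for isotropic data", {
  scheme <- tiny_scheme(n_dirs = 10, n_b0 = 2)
  vol <- one_voxel_volume(tensor_signal(scheme, rep(0.8e-3, 3)), scheme)
  tf <- fit_dti(vol, bmax = 900)
  d1 <- extract_directional_decay(vol, tf[1, ], 1)
  d2 <- extract_directional_decay(vol, tf[1, ], 2)
  d3 <- extract_directional_decay(vol, tf[1, ], 3)
  expect_equal(d1$sfrac, d2$sfrac, tolerance = 1e-9)
  expect_equal(d2$sfrac, d3$sfrac, tolerance = 1e-9)
})

test_that("projected decay agrees with a measured gradient direction", {
  # tensor whose primary axis coincides with one of the sampled gradient
  # directions: the projection must reproduce that direction's decay
  dirs <- generate_directions(12, seed = 5)
  u <- dirs[1, ]
  b <- c(rep(0, 3), rep(hmb_shells, each = 12))
  g <- rbind(matrix(0, 3, 3), dirs[rep(1:12, times = length(hmb_shells)), ])
  scheme <- gradient_scheme(b, g, 3.55, 8.52)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * u) * u
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(u[2] * e2[3] - u[3] * e2[2],
          u[3] * e2[1] - u[1] * e2[3],
          u[1] * e2[2] - u[2] * e2[1])
  R <- cbind(u, e2, e3)
  sig <- tensor_signal(scheme, c(1.9, 1.0, 0.6) * 1e-3, R)
  vol <- one_voxel_volume(sig, scheme)
  tf <- fit_dti(vol, bmax = 900)
  dec <- extract_directional_decay(vol, tf[1, ], 1)
  measured <- vapply(hmb_shells, function(bv) {
    idx <- which(scheme$b == bv &
                   abs(scheme$gx - u[1]) < 1e-12 &
                   abs(scheme$gy - u[2]) < 1e-12)[1]
    sig[idx] / 100
  }, numeric(1))
  expect_equal(dec$sfrac, measured, tolerance = 1e-6)
})

test_that("directional_decay validates its contract", {
  expect_error(directional_decay(c(100, 100), c(0.9, 0.8)), "increasing")
  expect_error(directional_decay(c(100, 200), c(0.9, 1.7)), "finite")
  expect_error(directional_decay(c(100, 200), c(0.9, -0.1)), "finite")
})
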