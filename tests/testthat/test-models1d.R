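test_that("mono-exponential fit is exact on its own model class", {
  dec <- directional_decay(hmb_shells, exp(-hmb_shells * 1e-3))
  fit <- fit_monoexp(dec)
  expect_equal(fit$D_app, 1e-3, tolerance = 1e-9)

  flat <- directional_decay(hmb_shells, rep(1, length(hmb_shells)))
  expect_equal(fit_monoexp(flat)$D_app, 0, tolerance = 1e-12)

  expect_error(fit_monoexp(directional_decay(100, 0.9)), ">= 2")
})

test_that("mono-exponential D_app on bi-exponential data sits between the rates", {
  r <- native_rates
  dec <- biexp_decay(hmb_shells[hmb_shells <= 900], r$v_f, r$D_f, r$D_s)
  d <- fit_monoexp(dec)$D_app
  expect_gt(d, r$D_s)
  expect_lt(d, r$D_f)
})

test_that("stretched-exponential fit honours bounds and nests the mono model", {
  mono <- directional_decay(hmb_shells, exp(-hmb_shells * 1.5e-3))
  st <- fit_stretched(mono)
  expect_equal(st$alpha, 1, tolerance = 1e-6)
  expect_equal(st$D_st, 1.5e-3, tolerance = 1e-6)

  gen <- directional_decay(hmb_shells, exp(-(hmb_shells^0.7) * 1e-3))
  st2 <- fit_stretched(gen)
  expect_equal(st2$alpha, 0.7, tolerance = 1e-4)
  expect_equal(st2$D_st, 1e-3, tolerance = 1e-4)

  # alpha never leaves [0.1, 1] even on noisy decays
  set.seed(77)
  for (rep in 1:20) {
    y <- exp(-(hmb_shells^runif(1, 0.3, 1)) * 10^runif(1, -3.5, -2.5))
    y <- pmin(pmax(y * (1 + rnorm(length(y), sd = 0.05)), 1e-3), 1.5)
    st3 <- fit_stretched(directional_decay(hmb_shells, y))
    expect_gte(st3$alpha, 0.1)
    expect_lte(st3$alpha, 1)
  }
  expect_error(fit_stretched(directional_decay(c(100, 200), c(0.9, 0.8))),
               ">= 3")
})

test_that("kurtosis fit nests the mono model and respects bmax", {
  mono <- directional_decay(hmb_shells, exp(-hmb_shells * 1e-3))
  ku <- fit_kurtosis_1d(mono)
  expect_equal(ku$K_app, 0, tolerance = 1e-6)
  expect_equal(ku$D_app, 1e-3, tolerance = 1e-9)

  # data above bmax are excluded: corrupting them does not change the fit
  r <- native_rates
  y <- r$v_f * exp(-r$D_f * hmb_shells) + (1 - r$v_f) * exp(-r$D_s * hmb_shells)
  y_bad <- y
  y_bad[hmb_shells > 2400] <- 1.4
  f1 <- fit_kurtosis_1d(directional_decay(hmb_shells, y))
  f2 <- fit_kurtosis_1d(directional_decay(hmb_shells, y_bad))
  expect_equal(f1$K_app, f2$K_app, tolerance = 1e-12)

  # exact recovery inside its own model class
  d_true <- 1.1e-3
  k_true <- 0.8
  bs <- hmb_shells[hmb_shells <= 2400]
  yk <- exp(-bs * d_true + bs^2 * d_true^2 * k_true / 6)
  fk <- fit_kurtosis_1d(directional_decay(bs, yk))
  expect_equal(fk$D_app, d_true, tolerance = 1e-8)
  expect_equal(fk$K_app, k_true, tolerance = 1e-6)
})

test_that("apparent kurtosis moves monotonically toward the cumulant limit as bmax shrinks", {
  r <- native_rates
  k_lim <- k_biexp_true(r$v_f, r$D_f, r$D_s)
  sweep_bmax <- c(2400, 1800, 1200, 600, 300, 100)
  ks <- vapply(sweep_bmax, function(bm) {
    bs <- seq(bm / 12, bm, length.out = 12)
    fit_kurtosis_1d(biexp_decay(bs, r$v_f, r$D_f, r$D_s), bmax = bm)$K_app
  }, numeric(1))
  expect_true(all(diff(ks) > 0))        # increasing toward the limit
  expect_true(all(ks < k_lim))
  expect_lt(k_lim - ks[length(ks)], 0.01)
})

test_that("bi-exponential fit recovers the native rates on noise-free data", {
  r <- native_rates
  dec <- biexp_decay(hmb_shells, r$v_f, r$D_f, r$D_s)
  fit <- fit_biexp(dec)
  expect_false(fit$degenerate)
  expect_equal(fit$v_f, r$v_f, tolerance = 1e-3)
  expect_equal(fit$D_f, r$D_f, tolerance = 1e-3)
  expect_equal(fit$D_s, r$D_s, tolerance = 1e-3)
})

test_that("bi-exponential fit flags the single-compartment degeneracy", {
  dec <- directional_decay(hmb_shells, exp(-hmb_shells * 1.2e-3))
  fit <- fit_biexp(dec)
  expect_true(fit$degenerate)
  expect_equal(fit$v_f, 1)
  expect_equal(fit$D_s, fit$D_f)
  expect_equal(fit$D_f, 1.2e-3, tolerance = 1e-4)
})

test_that("bi-exponential output always satisfies the model constraints", {
  set.seed(42)
  for (rep in 1:25) {
    vf <- runif(1, 0.2, 0.9)
    df <- 10^runif(1, -3.1, -2.7)
    ds <- df * runif(1, 0.05, 0.6)
    y <- vf * exp(-df * hmb_shells) + (1 - vf) * exp(-ds * hmb_shells)
    y <- pmin(pmax(y * (1 + rnorm(length(y), sd = 0.03)), 1e-3), 1.5)
    fit <- fit_biexp(directional_decay(hmb_shells, y))
    expect_equal(fit$v_f + fit$v_s, 1, tolerance = 1e-12)
    expect_gte(fit$D_f, fit$D_s)
    expect_gte(fit$D_s, 0)
  }
  expect_error(
    fit_biexp(biexp_decay(c(100, 300, 600, 900), 0.5, 1e-3, 1e-4)),
    "b_high"
  )
})

test_that("mono-exponential fit under-predicts bi-exponential signal at high b", {
  r <- native_rates
  dec <- biexp_decay(hmb_shells, r$v_f, r$D_f, r$D_s)
  low <- dec[dec$b <= 900, ]
  d_mono <- fit_monoexp(low)$D_app
  high <- dec$b > 1500
  predicted <- exp(-dec$b[high] * d_mono)
  expect_true(all(predicted < dec$sfrac[high]))
})
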