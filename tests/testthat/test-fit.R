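test_that("regressor closed form, log law, and non-regressable marking", {
  # frozen example: a = 2, b = 1 um at 10 kV/m
  expect_equal(build_regressor(1e4, 2, 1), log(1e8 / 1.375e6), tolerance = 1e-12)
  expect_equal(build_regressor(1e4, 2, 1), 4.2867, tolerance = 1e-4)
  # doubling the field raises x by exactly 2 ln 2
  expect_equal(build_regressor(2e4, 2, 1) - build_regressor(1e4, 2, 1),
               2 * log(2), tolerance = 1e-12)
  # E0 = 0, spheres, and oblate shapes are non-regressable, not errors
  expect_true(is.na(build_regressor(0, 2, 1)))
  expect_true(is.na(build_regressor(1e4, 1, 1)))
  expect_true(is.na(build_regressor(1e4, 1, 2)))
  # sum-vs-mean curvature convention shifts x by exactly -ln 2
  expect_equal(build_regressor(1e4, 2, 1, curvature_convention = "sum") -
                 build_regressor(1e4, 2, 1), -log(2), tolerance = 1e-12)
})

test_that("regime selection returns the whole series when it is globally linear", {
  ser <- fake_series(1e-3 * (1:12))
  w <- select_bending_regime(ser)
  expect_true(w$global)
  expect_equal(w$n, 12)
})

test_that("regime selection cuts a saturating tail at the change point", {
  ser <- saturating_series(n_lin = 10, n_tail = 5)
  w <- select_bending_regime(ser)
  expect_equal(c(w$lo, w$hi), c(1, 10))
})

test_that("pure-noise series yields no regime across seeds", {
  for (i in 1:10) {
    set.seed(300 + i)
    ser <- fake_series(abs(rnorm(20, 0.027, 0.002)))
    expect_error(select_bending_regime(ser), "no linear bending regime")
  }
  expect_error(select_bending_regime(fake_series(c(1, 2, 3) * 1e-3)),
               "need >= 4")
})

test_that("kappa follows the slope closed form with its invariances", {
  ser <- fake_series(3.638e-4 * (1:10) + 0.02)
  est <- fit_kappa(ser, temperature = 298, pixel_dev = 0)
  expect_identical(est$status, "ok")
  expect_equal(est$kappa, kB_codata * 298 / (8 * pi * 3.638e-4), tolerance = 1e-9)
  expect_equal(est$kappa, kappa_guv, tolerance = 1e-3)
  # doubling the response halves the stiffness exactly
  ser2 <- ser
  ser2$dA_over_A0 <- 2 * ser2$dA_over_A0
  expect_equal(fit_kappa(ser2, temperature = 298, pixel_dev = 0)$kappa,
               est$kappa / 2, tolerance = 1e-12)
  # stiffness is proportional to temperature for fixed data
  expect_equal(fit_kappa(ser, temperature = 596, pixel_dev = 0)$kappa,
               2 * est$kappa, tolerance = 1e-12)
})

test_that("curvature convention leaves the fitted stiffness unchanged", {
  ser <- generate_deformation_series(synthetic_config(seed = 77))
  e_mean <- fit_kappa(ser, curvature_convention = "mean")
  e_sum <- fit_kappa(ser, curvature_convention = "sum")
  expect_identical(e_mean$status, "ok")
  expect_lt(abs(e_sum$kappa - e_mean$kappa) / e_mean$kappa, 1e-12)
  # only the intercept moves: x drops by ln 2, so c absorbs +slope * ln 2
  expect_equal(e_sum$intercept_c - e_mean$intercept_c,
               e_mean$slope * log(2), tolerance = 1e-9)
})

test_that("estimator is calibrated when the regime is supplied", {
  # recovery without the qualifying gate: median bias < 2%, spread < 15%
  kaps <- vapply(1:80, function(i) {
    ser <- generate_deformation_series(synthetic_config(seed = 5000 + i))
    reg <- structure(list(lo = 1L, hi = sum(ser$regressable),
                          indices = which(ser$regressable),
                          r2 = NA, slope = NA, n = sum(ser$regressable),
                          global = TRUE), class = "regime_window")
    fit_kappa(ser, regime = reg)$kappa
  }, numeric(1))
  expect_lt(abs(stats::median(kaps) / kappa_guv - 1), 0.02)
  expect_lt(stats::sd(kaps / kappa_guv), 0.15)
})

test_that("non-positive slopes are reported as non-deforming, never negative kappa", {
  ser <- fake_series(rev(1e-3 * (1:10)))  # decreasing response
  est <- fit_kappa(ser)
  expect_identical(est$status, "non-deforming")
  expect_true(is.na(est$kappa))
})

test_that("pixel-error propagation follows 2*delta/D", {
  expect_equal(propagate_pixel_error(41.4, 0.29), 2 * 0.29 / 41.4)
  expect_equal(propagate_pixel_error(41.4, 0.29), 0.014, tolerance = 1e-3)
  expect_equal(propagate_pixel_error(20, 0.29), 0.029)
  expect_equal(propagate_pixel_error(41.4, 0), 0)
  expect_equal(propagate_pixel_error(vesicle("v", R0 = 20.7), 0.29),
               2 * 0.29 / 41.4)
})

test_that("aggregation averages defined estimates and counts non-deforming ones", {
  ok1 <- structure(list(kappa = 4e-19, status = "ok"), class = "kappa_estimate")
  ok2 <- structure(list(kappa = 5e-19, status = "ok"), class = "kappa_estimate")
  nd <- structure(list(kappa = NA_real_, status = "non-deforming"),
                  class = "kappa_estimate")
  agg <- aggregate_kappa(list(ok1, ok2))
  expect_equal(agg$kappa_mean, 4.5e-19)
  expect_equal(agg$kappa_sd, stats::sd(c(4e-19, 5e-19)))
  expect_equal(agg$kappa_sd, 7.0710678e-20, tolerance = 1e-6)
  agg2 <- aggregate_kappa(list(ok1, ok2, nd))
  expect_equal(agg2$n, 2)
  expect_equal(agg2$n_non_deforming, 1)
  expect_equal(agg2$kappa_mean, 4.5e-19)
  single <- aggregate_kappa(list(ok1))
  expect_true(is.na(single$kappa_sd))
  expect_error(aggregate_kappa(list(nd)), "no vesicle")
})
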