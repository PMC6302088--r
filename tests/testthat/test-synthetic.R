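test_that("noiseless generated series satisfies the forward model self-consistently", {
  cfg <- synthetic_config(noise_sd_dA = 0, field_grid = c(0, field_grid_default(12)),
                          seed = 3)
  ser <- generate_deformation_series(cfg)
  tr <- attr(ser, "truth")
  x <- build_regressor(ser$E0_V_per_m, ser$a_um, ser$b_um)
  reg <- ser$regressable
  # every stored point re-evaluates onto the generating line
  expect_lt(max(abs(ser$dA_over_A0[reg] - (tr$slope * x[reg] + tr$intercept_c))),
            1e-8)
  # deformation strictly increasing in field strength
  expect_true(all(diff(ser$dA_over_A0[reg]) > 0))
  # zero-field row: undeformed, flagged non-regressable
  z <- ser[ser$E0_V_per_m == 0, ]
  expect_equal(z$dA_over_A0, 0)
  expect_false(z$regressable)
  expect_equal(z$a_um, z$b_um)
})

test_that("generated slope equals kBT/(8 pi kappa) and the fit inverts it", {
  cfg <- synthetic_config(kappa_true = kappa_guv, T = 298, noise_sd_dA = 0, seed = 5)
  ser <- generate_deformation_series(cfg)
  tr <- attr(ser, "truth")
  expect_equal(tr$slope, kB_codata * 298 / (8 * pi * kappa_guv), tolerance = 1e-12)
  expect_equal(tr$slope, 3.638e-4, tolerance = 1e-4)
  est <- fit_kappa(ser, pixel_dev = 0)
  expect_identical(est$status, "ok")
  expect_equal(est$kappa, kappa_guv, tolerance = 1e-6)
  expect_equal(est$intercept_c, tr$intercept_c, tolerance = 1e-6)
})

test_that("generation is seed-deterministic and the noise is calibrated", {
  cfg <- synthetic_config(seed = 42)
  s1 <- generate_deformation_series(cfg)
  s2 <- generate_deformation_series(cfg)
  expect_identical(s1, s2)
  s3 <- generate_deformation_series(synthetic_config(seed = 43))
  expect_false(identical(s1$dA_over_A0, s3$dA_over_A0))
  # relative residual sd across seeds matches the configured 1.4% within 20%
  rel <- unlist(lapply(1:60, function(i) {
    ser <- generate_deformation_series(synthetic_config(seed = 9000 + i))
    tr <- attr(ser, "truth")
    reg <- ser$regressable
    (ser$dA_over_A0[reg] - tr$dA_clean[reg]) / tr$dA_clean[reg]
  }))
  expect_lt(abs(stats::sd(rel) - 0.014) / 0.014, 0.2)
})

test_that("population sampler respects truncation and matches the CDF oracle", {
  d <- generate_population(700, seed = 2)
  expect_length(d, 700)
  expect_true(all(d >= 10 & d <= 60))
  expect_identical(d, generate_population(700, seed = 2))
  # degenerate spread collapses to the median
  expect_equal(generate_population(50, median_um = 30, sigma_log = 1e-9, seed = 1),
               rep(30, 50), tolerance = 1e-6)
  # Kolmogorov-Smirnov distance against the analytic truncated CDF
  big <- generate_population(1e5, median_um = 25, sigma_log = 0.4, seed = 8)
  ecdf_fn <- stats::ecdf(big)
  grid <- seq(10, 60, length.out = 2001)
  ks <- max(abs(ecdf_fn(grid) -
                  guvkappa:::ptrunc_lnorm(grid, 25, 0.4, 10, 60)))
  expect_lt(ks, 0.01)
  expect_error(generate_population(10, min_um = 60, max_um = 10), "invalid")
})

test_that("rendered frames honour the optics contract and seeding", {
  ves <- vesicle("r", R0 = 7.25, pixel_size = 0.145)
  shp <- spheroid(7.5, 7.0)
  clean <- render_vesicle_frame(shp, ves,
                                optics = optics_default(noise_sd = 0, blur_sigma_px = 0),
                                seed = 1)
  img <- clean$intensity
  # ring pixels strictly darker than the background mean
  opt <- optics_default()
  ring <- img[abs(img - opt$ring_contrast) < 1e-9]
  expect_gt(length(ring), 0)
  expect_true(all(ring < mean(img[img > 0.6])))
  # interior and exterior at distinct levels
  ctr <- dim(img) / 2
  expect_lt(img[ctr[1], ctr[2]], 0.5)
  expect_gt(img[3, 3], 0.5)
  # same shape, different seeds: identical truth, different noise
  f1 <- render_vesicle_frame(shp, ves, seed = 10)
  f2 <- render_vesicle_frame(shp, ves, seed = 11)
  expect_identical(f1$truth, f2$truth)
  expect_false(identical(f1$intensity, f2$intensity))
  expect_identical(f1$intensity,
                   render_vesicle_frame(shp, ves, seed = 10)$intensity)
  # a circle of radius 50 px survives the full measurement round trip
  ves2 <- vesicle("c", R0 = 50 * 0.145, pixel_size = 0.145)
  fr <- render_vesicle_frame(spheroid(7.25, 7.25), ves2, seed = 4)
  seg <- segment_vesicle(fr)
  expect_lt(abs(seg$ellipse$a_px - 50), 0.5)
  expect_lt(abs(seg$ellipse$b_px - 50), 0.5)
  # an oversized shape cannot be rendered into a small frame
  expect_error(render_vesicle_frame(spheroid(30, 30), ves, frame_px = 64),
               "exceeds")
})
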