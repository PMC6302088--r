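disc_mask <- function(n, cx, cy, r) {
  col <- matrix(rep(0:(n - 1), each = n), n, n)
  row <- matrix(rep(0:(n - 1), times = n), n, n)
  ((col - cx)^2 + (row - cy)^2 <= r^2) * 1L
}

test_that("binarize recovers a two-level disc and rejects degenerate frames", {
  m <- disc_mask(101, 50, 50, 30)
  img <- 0.9 - 0.7 * m  # dark disc on bright background
  mask <- binarize(img, min_area_px = 10)
  expect_equal(sum(mask != m), 0)
  expect_error(binarize(matrix(0.5, 50, 50)), "constant")
  # speckle below min_area_px is removed
  img2 <- img
  img2[2:3, 2:3] <- 0.1
  expect_equal(sum(binarize(img2, min_area_px = 10) != m), 0)
  # a rendered vesicle yields exactly one component
  ves <- vesicle("b", R0 = 7.25, pixel_size = 0.145)
  fr <- render_vesicle_frame(spheroid(7.5, 7.0), ves, seed = 2)
  lab <- EBImage::bwlabel(EBImage::Image(binarize(fr)))
  expect_equal(max(EBImage::imageData(lab)), 1)
})

test_that("contour extraction is sub-pixel on discs and picks the largest component", {
  m <- disc_mask(101, 50, 50, 30)
  ct <- extract_contour(m)
  r <- sqrt((ct$x - 50)^2 + (ct$y - 50)^2)
  # mask boundary sits midway between pixel centers: half-pixel staircase
  expect_true(all(abs(r - 30) <= 0.5 + 1e-9))
  expect_lt(mean(abs(r - 30)), 0.35)
  # closed contour
  expect_equal(ct$x[1], ct$x[nrow(ct)])
  expect_equal(ct$y[1], ct$y[nrow(ct)])
  # two discs: the larger is chosen
  m2 <- disc_mask(201, 60, 60, 40) + disc_mask(201, 160, 160, 15)
  ct2 <- extract_contour(m2)
  expect_true(all(sqrt((ct2$x - 60)^2 + (ct2$y - 60)^2) < 45))
  # component touching the frame edge is flagged
  m3 <- disc_mask(60, 0, 30, 20)
  expect_warning(ct3 <- extract_contour(m3), "truncated")
  expect_true(attr(ct3, "truncated"))
})

test_that("ellipse fitting is exact on exact points and validates input", {
  t <- seq(0, 2 * pi, length.out = 101)[-101]
  th0 <- 0.4
  xy <- data.frame(
    x = 80 + 60 * cos(t) * cos(th0) - 40 * sin(t) * sin(th0),
    y = 90 + 60 * cos(t) * sin(th0) + 40 * sin(t) * cos(th0))
  e <- fit_ellipse(xy)
  expect_equal(e$a_px, 60, tolerance = 1e-6)
  expect_equal(e$b_px, 40, tolerance = 1e-6)
  expect_equal(e$cx, 80, tolerance = 1e-6)
  expect_equal(e$cy, 90, tolerance = 1e-6)
  expect_equal(e$theta, th0, tolerance = 1e-6)
  # circle: equal axes, any orientation
  circ <- data.frame(x = 10 + 5 * cos(t), y = 10 + 5 * sin(t))
  ec <- fit_ellipse(circ)
  expect_equal(ec$a_px, ec$b_px, tolerance = 1e-6)
  expect_error(fit_ellipse(data.frame(x = 1:10, y = 2 * (1:10))), "degenerate|collinear")
  expect_error(fit_ellipse(data.frame(x = 1:5, y = c(1, 3, 2, 5, 4))), "6 points")
})

test_that("axes measured from a rendered stack reproduce the generating series", {
  cfg <- synthetic_config(R0 = 14.5, noise_sd_dA = 0,
                          field_grid = c(0, field_grid_default(8)), seed = 21)
  ser <- generate_deformation_series(cfg)
  st <- render_series(ser, seed = 210)
  mes <- measure_axes(st)
  expect_equal(nrow(mes), nrow(ser))
  # zero-field frame has dA = 0 by construction
  expect_equal(mes$dA_over_A0[mes$E0_V_per_m == 0], 0)
  # recovered area changes within 1% (relative) of the generating ones
  reg <- ser$regressable
  expect_lt(max(abs(mes$dA_over_A0[reg] - ser$dA_over_A0[reg]) /
                  ser$dA_over_A0[reg]), 0.01)
  # recovered radius matches
  expect_equal(attr(mes, "vesicle")$R0, 14.5, tolerance = 1e-2)
  # a stack without any zero-field frame cannot be referenced
  st2 <- st
  st2$E0_V_per_m <- pmax(st2$E0_V_per_m, 1)
  expect_error(measure_axes(st2), "zero-field")
})

test_that("field-axis assignment follows the stated convention", {
  # prolate along x: with field on x, a > b; with field on y, axes swap
  ves <- vesicle("ax", R0 = 10, pixel_size = 0.145)
  fr0 <- render_vesicle_frame(spheroid(10, 10), ves, seed = 1)
  fr1 <- render_vesicle_frame(spheroid(11, 9.5), ves, seed = 2)
  stack <- list(frames = list(fr0, fr1), E0_V_per_m = c(0, 5000),
                pixel_size = 0.145)
  mx <- measure_axes(stack, field_axis = "x")
  expect_gt(mx$a_um[mx$E0_V_per_m > 0], mx$b_um[mx$E0_V_per_m > 0])
  my <- measure_axes(stack, field_axis = "y")
  expect_lt(my$a_um[my$E0_V_per_m > 0], my$b_um[my$E0_V_per_m > 0])
})

test_that("rotating a frame by 90 degrees permutes the recovered axes", {
  ves <- vesicle("rot", R0 = 10, pixel_size = 0.145)
  fr <- render_vesicle_frame(spheroid(12, 9), ves, seed = 5)
  seg <- segment_vesicle(fr)
  rot <- t(fr$intensity)[, rev(seq_len(nrow(fr$intensity)))]  # 90 deg CCW
  segr <- segment_vesicle(structure(list(intensity = rot, pixel_size = 0.145),
                                    class = "image_frame"))
  expect_equal(segr$ellipse$a_px, seg$ellipse$a_px, tolerance = 0.1)
  expect_equal(segr$ellipse$b_px, seg$ellipse$b_px, tolerance = 0.1)
  expect_equal(min(abs(c(segr$ellipse$theta - seg$ellipse$theta - pi / 2,
                         segr$ellipse$theta - seg$ellipse$theta + pi / 2))),
               0, tolerance = 0.05)
})

test_that("equivalent diameter follows the closed forms and scales with pixel size", {
  expect_equal(equivalent_diameter(pi * 50^2, 0.145), 14.5)
  ell <- structure(list(cx = 0, cy = 0, a_px = 60, b_px = 40, theta = 0),
                   class = "ellipse_fit")
  expect_equal(equivalent_diameter(ell, 1, method = "axes"), 2 * sqrt(2400))
  expect_equal(equivalent_diameter(ell, 1), 2 * sqrt(2400), tolerance = 1e-12)
  m <- disc_mask(101, 50, 50, 30)
  d1 <- equivalent_diameter(m, 0.145)
  expect_equal(d1, 2 * sqrt(sum(m) / pi) * 0.145)
  # scale covariance: doubling pixel size doubles micron outputs exactly
  expect_equal(equivalent_diameter(m, 0.29), 2 * d1)
  expect_error(equivalent_diameter(0, 0.145), "area")
})

test_that("size distributions count every diameter exactly once", {
  sd3 <- size_distribution(c(10, 10, 20), bin_width = 5)
  expect_equal(sd3$mean, 13.3333333, tolerance = 1e-6)
  expect_equal(sd3$sd, 5.7735027, tolerance = 1e-6)
  expect_equal(sum(sd3$counts), 3)
  # value on the last edge is counted (closed last bin)
  s <- size_distribution(c(10, 15, 20), edges = c(10, 15, 20))
  expect_equal(sum(s$counts), 3)
  expect_equal(s$counts, c(1, 2))
  single <- size_distribution(42)
  expect_equal(sum(single$counts > 0), 1)
  expect_true(is.na(single$sd))
  expect_error(size_distribution(c(5, 10), edges = c(10, 20)), "outside")
  expect_error(size_distribution(numeric(0)), "at least one")
})
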