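# Independent numerical oracles and fixture builders used across the suite.

# Surface-of-revolution quadrature for the spheroid area: profile
# r(t) = b sin t, z(t) = a cos t, t in [0, pi].
area_quadrature <- function(a, b) {
  f <- function(t) 2 * pi * b * sin(t) * sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  stats::integrate(f, 0, pi, rel.tol = 1e-12, abs.tol = 0)$value
}

# Principal curvatures of the meridian profile at parameter t, from the
# parametrized surface (independent of the closed forms under test).
curvatures_numeric <- function(a, b, t) {
  r <- b * sin(t);  z <- a * cos(t)
  r1 <- b * cos(t); z1 <- -a * sin(t)
  r2 <- -b * sin(t); z2 <- -a * cos(t)
  km <- abs(r1 * z2 - z1 * r2) / (r1^2 + z1^2)^(3 / 2)
  kp <- abs(z1) / (r * sqrt(r1^2 + z1^2))
  c(meridian = km, parallel = kp)
}

mean_curvature_numeric <- function(a, b, t) mean(curvatures_numeric(a, b, t))

# A deformation series carrying arbitrary (x implied by shape, y) values:
# fixed prolate shape per row so the regressor spacing is controlled by E0.
fake_series <- function(dA, x_spacing = 1, a = 2, b = 1, id = "fake") {
  n <- length(dA)
  # regressor x = ln(E0^2/const): choose E0 = exp((x0 + i*dx)/2)
  E0 <- exp((seq_len(n) * x_spacing + 20) / 2)
  out <- data.frame(
    vesicle_id = id, E0_V_per_m = E0, frequency_Hz = 1e5,
    a_um = a, b_um = b, dA_over_A0 = dA, regressable = TRUE,
    stringsAsFactors = FALSE
  )
  structure(out,
            vesicle = vesicle(id, R0 = (a * b^2)^(1 / 3)),
            environment = environment_spec(),
            class = c("deformation_series", "data.frame"))
}

# Linear response of known slope on the regressor scale, plus a flat
# (saturated) tail of `n_tail` records appended at higher fields.
saturating_series <- function(n_lin = 10, n_tail = 5, slope = 1e-3) {
  x <- seq_len(n_lin + n_tail)
  y <- c(slope * seq_len(n_lin), rep(slope * n_lin, n_tail))
  fake_series(y)
}

kB_codata <- 1.380649e-23
kappa_guv <- 4.5e-19   # pure-GUV bending stiffness used as generating truth
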