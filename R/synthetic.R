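# Run code with a local, restored RNG state so generator seeding never
# disturbs the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Configuration of the synthetic electrodeformation generator
#'
#' Collects every parameter of the forward model used to synthesize
#' deformation experiments with known ground truth: the generating bending
#' stiffness, the intercept of the bending-regime line, the thermal
#' environment, the applied-field grid, and the measurement-noise model.
#'
#' The defaults emulate the study conditions of a pure-GUV experiment: a
#' bending stiffness of 4.5e-19 J, an AC frequency of 100 kHz, 20
#' log-spaced field strengths spanning 100 to 20,000 V/m, a vesicle radius
#' of 20.7 µm (diameter 41.4 µm), and an axis-measurement deviation of two
#' pixels (0.29 µm at 0.145 µm/px), which propagates to a ±1.4% relative
#' uncertainty of the apparent-area change.
#'
#' @param kappa_true Generating bending stiffness (J), > 0.
#' @param intercept_c Intercept of the bending-regime line (dimensionless).
#'   `NULL` (default) calibrates it so that ΔA/A0 = `dA_at_max` at the
#'   largest field in `field_grid` — a small-deformation regime.
#' @param T Temperature (K).
#' @param kB Boltzmann constant (J/K).
#' @param field_grid Applied field strengths E0 (V/m). `E0 = 0` entries are
#'   carried through as undeformed, non-regressable rows.
#' @param frequency AC frequency (Hz); bookkeeping only — its physical
#'   effect is the (configurable) intercept.
#' @param noise_sd_dA Measurement noise on ΔA/A0. With
#'   `noise_model = "relative"` (default) the per-point Gaussian sd is
#'   `noise_sd_dA * dA` (a ±1.4% relative area-change uncertainty when 0.014);
#'   with `"absolute"` it is `noise_sd_dA` itself.
#' @param noise_model `"relative"` or `"absolute"`.
#' @param pixel_dev Axis-measurement deviation (µm); two pixels = 0.29 µm.
#' @param R0 Unperturbed vesicle radius (µm).
#' @param pixel_size µm per pixel.
#' @param dA_at_max Target ΔA/A0 at the largest field used when
#'   auto-calibrating `intercept_c`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(kappa_true = 4.5e-19,
                             intercept_c = NULL,
                             T = 298,
                             kB = 1.380649e-23,
                             field_grid = field_grid_default(),
                             frequency = 1e5,
                             noise_sd_dA = 0.014,
                             noise_model = c("relative", "absolute"),
                             pixel_dev = 0.29,
                             R0 = 20.7,
                             pixel_size = 0.145,
                             dA_at_max = 0.03,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(kappa_true), kappa_true > 0,
            is.numeric(T), T > 0, is.numeric(kB), kB > 0,
            is.numeric(field_grid), length(field_grid) >= 1L, all(field_grid >= 0),
            is.numeric(noise_sd_dA), noise_sd_dA >= 0,
            is.numeric(pixel_dev), pixel_dev >= 0,
            is.numeric(R0), R0 > 0, is.numeric(pixel_size), pixel_size > 0,
            is.numeric(dA_at_max), dA_at_max > 0)
  structure(list(
    kappa_true = kappa_true, intercept_c = intercept_c, T = T, kB = kB,
    field_grid = as.numeric(field_grid), frequency = frequency,
    noise_sd_dA = noise_sd_dA, noise_model = noise_model,
    pixel_dev = pixel_dev, R0 = R0, pixel_size = pixel_size,
    dA_at_max = dA_at_max, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default applied-field grid
#'
#' Twenty log-spaced field strengths covering 100 to 20,000 V/m, the upper
#' end of the experimental 0–20 kV/m sweep. Zero field is excluded because
#' `ln(E0^2)` diverges there; undeformed reference rows can be added
#' explicitly.
#'
#' @param n Number of field values.
#' @param min,max Range (V/m).
#' @return Numeric vector of field strengths.
#' @export
field_grid_default <- function(n = 20, min = 100, max = 20000) {
  exp(seq(log(min), log(max), length.out = n))
}

# Bending-regime slope s = kB*T / (8*pi*kappa).
bending_slope <- function(kappa, T, kB = 1.380649e-23) kB * T / (8 * pi * kappa)

# Regressor x = ln(E0^2 / (Hpo - Heq)) evaluated in SI units (E0 in V/m,
# curvatures converted from 1/µm to 1/m). The dimensional constant inside
# the log is absorbed into the intercept.
regressor_of_shape <- function(E0, shape) {
  dH_um <- mean_curvature_pole(shape) - mean_curvature_equator(shape)
  if (!is.finite(dH_um) || dH_um <= 0 || E0 <= 0) return(NA_real_)
  log(E0^2 / (dH_um * 1e6))
}

# Solve the self-consistent deformation d = s*ln(E0^2/(Hpo(d)-Heq(d))) + c
# for one field strength. The RHS decreases in d (the curvature difference
# grows with deformation), so the fixed point is unique.
solve_deformation <- function(E0, R0, slope, intercept, d_max = 0.2) {
  g <- function(d) {
    shape <- deform_at_fixed_volume(R0, d, "prolate")
    d - (slope * regressor_of_shape(E0, shape) + intercept)
  }
  lo <- 1e-8
  if (g(lo) > 0) {
    stop(sprintf("generate_deformation_series: no fixed point for E0 = %g V/m (deformation would be <= 0; intercept too low?)", E0),
         call. = FALSE)
  }
  if (g(d_max) < 0) {
    stop(sprintf("generate_deformation_series: no fixed point for E0 = %g V/m in (0, %g]", E0, d_max),
         call. = FALSE)
  }
  stats::uniroot(g, lower = lo, upper = d_max, tol = 1e-12)$root
}

# Calibrate the intercept so the noiseless deformation at the largest field
# equals dA_at_max.
calibrate_intercept <- function(config) {
  if (!is.null(config$intercept_c)) return(config$intercept_c)
  E0max <- max(config$field_grid[config$field_grid > 0])
  s <- bending_slope(config$kappa_true, config$T, config$kB)
  shape <- deform_at_fixed_volume(config$R0, config$dA_at_max, "prolate")
  config$dA_at_max - s * regressor_of_shape(E0max, shape)
}

#' Generate a synthetic electrodeformation series
#'
#' Forward-simulates one vesicle's response to the field grid of `config`
#' under the bending-regime relation: for each field strength the
#' self-consistent apparent-area change is solved (the regressor depends on
#' the deformed shape, which depends on the area change), measurement noise
#' is added, and the corresponding fixed-volume prolate semi-axes are
#' recorded. Zero-field rows are carried as undeformed and flagged
#' non-regressable. Deterministic given `config$seed`.
#'
#' @param vesicle A [vesicle()]; defaults to one built from `config$R0` and
#'   `config$pixel_size`.
#' @param config A [synthetic_config()].
#' @return A `data.frame` of class `"deformation_series"` with columns
#'   `vesicle_id`, `E0_V_per_m`, `frequency_Hz`, `a_um`, `b_um`,
#'   `dA_over_A0`, `regressable`, and attributes `vesicle`, `environment`
#'   (class `environment_spec`), and `truth` (generating slope, intercept,
#'   kappa, and the noiseless ΔA/A0 values).
#' @export
generate_deformation_series <- function(config, vesicle = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(vesicle)) {
    vesicle <- vesicle(id = "synthetic", R0 = config$R0,
                       pixel_size = config$pixel_size)
  }
  s <- bending_slope(config$kappa_true, config$T, config$kB)
  intercept <- calibrate_intercept(config)
  E0 <- config$field_grid
  n <- length(E0)

  d_clean <- numeric(n)
  for (i in seq_len(n)) {
    d_clean[i] <- if (E0[i] > 0) {
      solve_deformation(E0[i], vesicle$R0, s, intercept)
    } else 0
  }

  d_noisy <- with_seed(config$seed, {
    sd_pt <- switch(config$noise_model,
                    relative = config$noise_sd_dA * d_clean,
                    absolute = rep(config$noise_sd_dA, n))
    sd_pt[E0 <= 0] <- 0
    d_clean + stats::rnorm(n, 0, sd_pt)
  })

  a <- b <- numeric(n)
  regressable <- logical(n)
  dA <- pmax(d_noisy, 0)
  for (i in seq_len(n)) {
    if (E0[i] > 0 && d_noisy[i] > 0) {
      shp <- deform_at_fixed_volume(vesicle$R0, d_noisy[i], "prolate")
      a[i] <- shp$a; b[i] <- shp$b
      regressable[i] <- TRUE
    } else {
      a[i] <- b[i] <- vesicle$R0
      regressable[i] <- FALSE
    }
  }

  out <- data.frame(
    vesicle_id = vesicle$id,
    E0_V_per_m = E0,
    frequency_Hz = config$frequency,
    a_um = a,
    b_um = b,
    dA_over_A0 = dA,
    regressable = regressable,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$E0_V_per_m), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            vesicle = vesicle,
            environment = environment_spec(T = config$T, kB = config$kB),
            truth = list(kappa_true = config$kappa_true, slope = s,
                         intercept_c = intercept,
                         dA_clean = d_clean[order(E0)],
                         seed = config$seed),
            class = c("deformation_series", "data.frame"))
}

#' Sample a vesicle diameter population
#'
#' Draws diameters from a truncated log-normal distribution by inverse-CDF
#' sampling, emulating the 10–60 µm dispersion of electroswelling
#' preparations. Deterministic given `seed`.
#'
#' @param n Number of vesicles, > 0.
#' @param median_um Median of the untruncated log-normal (µm).
#' @param sigma_log Log-scale standard deviation, > 0.
#' @param min_um,max_um Truncation bounds (µm), `min_um < max_um`.
#' @param seed Integer seed.
#' @return Numeric vector of `n` diameters in `[min_um, max_um]`.
#' @export
generate_population <- function(n, median_um = 25, sigma_log = 0.4,
                                min_um = 10, max_um = 60, seed = 1L) {
  stopifnot(is.numeric(n), n > 0, n == round(n))
  if (!is.numeric(median_um) || median_um <= 0 || !is.numeric(sigma_log) ||
      sigma_log < 0 || !is.numeric(min_um) || !is.numeric(max_um) ||
      min_um <= 0 || min_um >= max_um) {
    stop("invalid population distribution parameters", call. = FALSE)
  }
  mu <- log(median_um)
  if (sigma_log == 0) {
    d0 <- min(max(median_um, min_um), max_um)
    return(rep(d0, n))
  }
  plo <- stats::plnorm(min_um, mu, sigma_log)
  phi <- stats::plnorm(max_um, mu, sigma_log)
  with_seed(seed, {
    u <- stats::runif(n, plo, phi)
    stats::qlnorm(u, mu, sigma_log)
  })
}

# CDF of the truncated log-normal (oracle for distributional tests).
ptrunc_lnorm <- function(q, median_um, sigma_log, min_um, max_um) {
  mu <- log(median_um)
  plo <- stats::plnorm(min_um, mu, sigma_log)
  phi <- stats::plnorm(max_um, mu, sigma_log)
  p <- (stats::plnorm(q, mu, sigma_log) - plo) / (phi - plo)
  pmin(pmax(p, 0), 1)
}

#' Default phase-contrast optics for the renderer
#'
#' Intensity levels, membrane ring geometry, blur, and pixel noise of the
#' synthetic phase-contrast appearance. The contrast levels are symmetric
#' about mid-gray so that a global Otsu threshold crosses the rendered
#' membrane edge at the ground-truth boundary.
#'
#' @param ring_width_px Width of the dark membrane ring (px), drawn just
#'   inside the boundary.
#' @param ring_contrast Intensity of the ring (dark).
#' @param halo_contrast Intensity of the bright halo just outside the
#'   boundary.
#' @param interior_level,background_level Interior / exterior mean levels
#'   (the sucrose-filled interior images darker than the glucose bath).
#' @param halo_width_px Width of the halo band (px).
#' @param blur_sigma_px Gaussian edge width (px) emulating optical blur.
#' @param noise_sd Additive Gaussian pixel noise sd (intensity units).
#' @return A list of optics parameters.
#' @export
optics_default <- function(ring_width_px = 3, ring_contrast = 0.08,
                           halo_contrast = 0.92, interior_level = 0.35,
                           background_level = 0.65, halo_width_px = 3,
                           blur_sigma_px = 0.8, noise_sd = 0.02) {
  list(ring_width_px = ring_width_px, ring_contrast = ring_contrast,
       halo_contrast = halo_contrast, interior_level = interior_level,
       background_level = background_level, halo_width_px = halo_width_px,
       blur_sigma_px = blur_sigma_px, noise_sd = noise_sd)
}

#' Render a phase-contrast-like frame of a vesicle
#'
#' Synthesizes the phase-contrast appearance of one spheroidal vesicle
#' projected along the optical axis: a dark membrane ring just inside the
#' ellipse boundary, a bright halo just outside it (the refractive-index
#' mismatch artifact), a darker interior, and a mid-gray background. Edges
#' are rendered as analytic Gaussian profiles of the signed distance to the
#' boundary — equivalent to blurring the ideal image whenever the boundary
#' curvature radius is large against `blur_sigma_px` — and i.i.d. Gaussian
#' pixel noise is added last.
#'
#' @param shape A [spheroid()]; its `a` axis lies along image x (columns).
#' @param vesicle A [vesicle()] supplying the pixel size.
#' @param optics Optics parameters, see [optics_default()].
#' @param frame_px Frame side length (px). `NULL` sizes the frame to the
#'   vesicle plus margin.
#' @param margin_px Minimum clearance between the vesicle and frame edge.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `"image_frame"`: list with `intensity`
#'   (rows x cols matrix in [0, 1]), `pixel_size`, and `truth` (ground-truth
#'   ellipse: center `cx`, `cy` in 0-based px, semi-axes `a_px`, `b_px`,
#'   orientation `theta`).
#' @export
render_vesicle_frame <- function(shape, vesicle, optics = optics_default(),
                                 frame_px = NULL, margin_px = 20, seed = 1L) {
  shape <- as_spheroid(shape)
  ps <- vesicle$pixel_size
  a_px <- shape$a / ps
  b_px <- shape$b / ps
  need <- 2 * (max(a_px, b_px) + optics$halo_width_px + margin_px)
  if (is.null(frame_px)) frame_px <- 2L * as.integer(ceiling(need / 2))
  if (frame_px < need) {
    stop(sprintf("render_vesicle_frame: shape (%.1f px semi-axis) exceeds frame %d px with %g px margin",
                 max(a_px, b_px), frame_px, margin_px), call. = FALSE)
  }
  nr <- nc <- as.integer(frame_px)
  cx <- (nc - 1) / 2
  cy <- (nr - 1) / 2

  # signed distance to the ellipse boundary: first-order estimate
  # (rho - 1)/|grad rho| everywhere, refined to the exact Euclidean
  # distance near the boundary (Newton on the eccentric angle), where the
  # rendered edge profiles live
  col <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  row <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  xr <- (col - cx)
  yr <- (row - cy)
  rho <- sqrt((xr / a_px)^2 + (yr / b_px)^2)
  grho <- sqrt((xr / a_px^2)^2 + (yr / b_px^2)^2) / pmax(rho, 1e-12)
  ds <- (rho - 1) / pmax(grho, 1e-12)
  ds[rho < 1e-12] <- -min(a_px, b_px)
  band <- which(abs(ds) < (optics$ring_width_px + optics$halo_width_px +
                             6 * optics$blur_sigma_px + 4))
  if (length(band) > 0) {
    ds[band] <- sign(rho[band] - 1) *
      ellipse_distance(abs(xr[band]), abs(yr[band]), a_px, b_px)
  }

  w <- optics$ring_width_px
  wh <- optics$halo_width_px
  sig <- optics$blur_sigma_px
  edge <- function(d) {
    if (sig > 0) stats::pnorm(d / sig) else (d > 0) + 0
  }
  lvl_in <- optics$interior_level
  lvl_ring <- optics$ring_contrast
  lvl_halo <- optics$halo_contrast
  lvl_bg <- optics$background_level
  img <- lvl_in +
    (lvl_ring - lvl_in) * edge(ds + w) +
    (lvl_halo - lvl_ring) * edge(ds) +
    (lvl_bg - lvl_halo) * edge(ds - wh)

  if (optics$noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, optics$noise_sd), nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(
    intensity = img,
    pixel_size = ps,
    truth = list(cx = cx, cy = cy, a_px = a_px, b_px = b_px, theta = 0)
  ), class = "image_frame")
}

# Exact unsigned distance from points (p, q) in the first quadrant to the
# axis-aligned ellipse with semi-axes (a, b): Newton iteration on the
# eccentric angle t of the nearest boundary point.
ellipse_distance <- function(p, q, a, b) {
  t <- atan2(a * q, b * p)
  for (i in 1:40) {
    ct <- cos(t); st <- sin(t)
    f <- (a^2 - b^2) * ct * st - p * a * st + q * b * ct
    fp <- (a^2 - b^2) * (ct^2 - st^2) - p * a * ct - q * b * st
    step <- f / fp
    step[!is.finite(step)] <- 0
    t <- pmin(pmax(t - step, 0), pi / 2)
    if (max(abs(step)) < 1e-12) break
  }
  sqrt((p - a * cos(t))^2 + (q - b * sin(t))^2)
}

#' Render a deformation series as an image stack
#'
#' Renders every row of a deformation series as one phase-contrast-like
#' frame (field along image x), producing the input of the imaging route.
#' Per-frame noise seeds are derived from `seed`.
#'
#' @param series A `deformation_series`.
#' @param optics See [optics_default()].
#' @param frame_px Common frame side (px); `NULL` auto-sizes to the largest
#'   shape in the series.
#' @param seed Integer seed.
#' @return List of class `"image_stack"`: `frames` (list of `image_frame`),
#'   `E0_V_per_m`, `pixel_size`.
#' @export
render_series <- function(series, optics = optics_default(), frame_px = NULL,
                          seed = 1L) {
  stopifnot(inherits(series, "deformation_series"))
  ves <- attr(series, "vesicle")
  if (is.null(frame_px)) {
    amax <- max(series$a_um, series$b_um) / ves$pixel_size
    frame_px <- 2L * as.integer(ceiling((2 * (amax + optics$halo_width_px + 20)) / 2))
  }
  frames <- vector("list", nrow(series))
  for (i in seq_len(nrow(series))) {
    frames[[i]] <- render_vesicle_frame(
      spheroid(series$a_um[i], series$b_um[i]), ves, optics,
      frame_px = frame_px, seed = seed + i - 1L)
  }
  structure(list(frames = frames, E0_V_per_m = series$E0_V_per_m,
                 frequency_Hz = series$frequency_Hz,
                 pixel_size = ves$pixel_size, vesicle = ves),
            class = "image_stack")
}
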