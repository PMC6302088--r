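#' Bending-regime regressor
#'
#' Builds the regressor `x = ln(E0^2 / (Hpo - Heq))` of the bending-regime
#' relation, with the field strength in V/m and the pole/equator curvature
#' difference converted to 1/m. Records with `E0 <= 0` or a non-prolate
#' shape (`Hpo <= Heq`) get `NA` — they are non-regressable, not errors.
#' Multiplying the curvature difference by any positive constant (e.g. the
#' sum rather than the mean of principal curvatures) shifts `x` by an
#' additive constant that the fit absorbs into its intercept, leaving the
#' slope — hence the bending stiffness — unchanged.
#'
#' @param E0 Field strength (V/m), scalar or vector.
#' @param a_um,b_um Semi-axes (µm), recycled against `E0`.
#' @param curvature_convention `"mean"` (`H = (c1+c2)/2`, default) or
#'   `"sum"` (`H = c1+c2`).
#' @return Numeric vector of regressor values (`NA` = non-regressable).
#' @export
build_regressor <- function(E0, a_um, b_um,
                            curvature_convention = c("mean", "sum")) {
  curvature_convention <- match.arg(curvature_convention)
  n <- max(length(E0), length(a_um), length(b_um))
  E0 <- rep_len(E0, n); a_um <- rep_len(a_um, n); b_um <- rep_len(b_um, n)
  fac <- if (curvature_convention == "sum") 2 else 1
  vapply(seq_len(n), function(i) {
    if (!is.finite(E0[i]) || E0[i] <= 0 ||
        !is.finite(a_um[i]) || !is.finite(b_um[i]) ||
        a_um[i] <= 0 || b_um[i] <= 0) {
      return(NA_real_)
    }
    shp <- spheroid(a_um[i], b_um[i])
    dH <- mean_curvature_pole(shp) - mean_curvature_equator(shp)
    if (dH <= 0) return(NA_real_)
    log(E0[i]^2 / (fac * dH * 1e6))
  }, numeric(1))
}

# Windowed OLS scan: cumulative-sum O(1) per window statistics.
window_stats <- function(x, y, lo, hi) {
  n <- hi - lo + 1
  xs <- x[lo:hi]; ys <- y[lo:hi]
  sxx <- sum((xs - mean(xs))^2)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  syy <- sum((ys - mean(ys))^2)
  if (sxx <= 0 || syy <= 0) {
    return(list(slope = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  rss <- syy - sxy^2 / sxx
  p <- if (n > 2) {
    if (rss <= .Machine$double.eps * syy) {
      0
    } else {
      se <- sqrt(rss / (n - 2) / sxx)
      2 * stats::pt(-abs(slope / se), df = n - 2)
    }
  } else NA_real_
  list(slope = slope, r2 = r2, p = p, n = n)
}

#' Select the bending regime of a deformation series
#'
#' The bending regime is the low-tension, log-linear stretch of the
#' response where flattening of thermal wrinkles dominates. Selection is
#' deterministic: if the whole series is already linear (R² >= `r2_global`)
#' it is returned outright; otherwise all contiguous windows of at least
#' `min_len` regressable records are scanned and the window maximizing R²
#' is chosen. Windows whose misfit `1 - R²` is within `tie_factor` times
#' the best misfit are treated as statistically tied — R² differences on
#' that scale are sampling noise — and the tie is broken toward the longer
#' and then the lower-field window. This keeps the scan from favouring
#' spuriously steep short windows under measurement noise while still
#' cutting a saturating tail exactly (a flat tail inflates the misfit far
#' beyond the tied band). A window only qualifies if its R² reaches
#' `r2_min` and its slope is significant under a two-sided t-test at level
#' `alpha` Bonferroni-corrected for the number of windows scanned (so a
#' pure-noise series does not yield a spurious regime). If no window
#' qualifies the vesicle is reported unfit.
#'
#' @param series A `deformation_series`, or a list/data.frame with
#'   regressor `x` and response `y`.
#' @param min_len Minimum window length (records).
#' @param r2_global Whole-series R² short-circuit threshold.
#' @param r2_min Minimum window R².
#' @param tie_factor Misfit multiple within which windows count as tied.
#' @param alpha Slope-significance level before the scan correction.
#' @param curvature_convention Passed to [build_regressor()].
#' @return List of class `"regime_window"`: `lo`, `hi` (indices into the
#'   regressable subset), `indices` (row indices of `series`), `r2`,
#'   `slope`, `n`, `global` (logical).
#' @export
select_bending_regime <- function(series, min_len = 4, r2_global = 0.98,
                                  r2_min = 0.9, tie_factor = 2, alpha = 0.05,
                                  curvature_convention = c("mean", "sum")) {
  curvature_convention <- match.arg(curvature_convention)
  xy <- regression_frame(series, curvature_convention)
  x <- xy$x; y <- xy$y
  n <- length(x)
  if (n < min_len) {
    stop(sprintf("select_bending_regime: %d regressable records, need >= %d", n, min_len),
         call. = FALSE)
  }
  ord <- order(x)  # ascending regressor = ascending field
  x <- x[ord]; y <- y[ord]
  idx <- xy$indices[ord]

  full <- window_stats(x, y, 1, n)
  if (is.finite(full$r2) && full$r2 >= r2_global) {
    return(structure(list(lo = 1L, hi = n, indices = idx, r2 = full$r2,
                          slope = full$slope, n = n, global = TRUE),
                     class = "regime_window"))
  }

  wins <- list()
  for (L in seq(min_len, n)) {
    for (lo in seq_len(n - L + 1)) {
      wins[[length(wins) + 1L]] <- c(lo, lo + L - 1L)
    }
  }
  n_win <- length(wins)
  alpha_adj <- alpha / n_win
  quals <- list()
  for (w in wins) {
    st <- window_stats(x, y, w[1], w[2])
    if (!is.finite(st$r2) || st$r2 < r2_min) next
    if (!is.finite(st$p) || st$p > alpha_adj) next
    quals[[length(quals) + 1L]] <-
      list(lo = w[1], hi = w[2], r2 = st$r2, slope = st$slope, n = st$n)
  }
  best <- NULL
  if (length(quals) > 0) {
    misfit_min <- min(vapply(quals, function(q) 1 - q$r2, numeric(1)))
    for (cand in quals) {
      if ((1 - cand$r2) > tie_factor * misfit_min + 1e-12) next
      if (is.null(best) ||
          cand$n > best$n ||
          (cand$n == best$n && cand$r2 > best$r2 + 1e-10) ||
          (cand$n == best$n && abs(cand$r2 - best$r2) <= 1e-10 &&
           cand$lo < best$lo)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("select_bending_regime: no linear bending regime found (vesicle unfit)",
         call. = FALSE)
  }
  structure(list(lo = best$lo, hi = best$hi,
                 indices = idx[best$lo:best$hi],
                 r2 = best$r2, slope = best$slope, n = best$n, global = FALSE),
            class = "regime_window")
}

#' Fit the bending stiffness from a deformation series
#'
#' Ordinary least squares of ΔA/A0 on the bending-regime regressor over the
#' selected regime; the slope `s = kB*T/(8*pi*kappa)` converts to the
#' bending stiffness `kappa = kB*T/(8*pi*s)`. The uncertainty is first
#' order (delta method) in the slope standard error; an axis-measurement
#' noise floor from [propagate_pixel_error()] is added in quadrature to the
#' residual-based slope SE. A non-positive slope yields a "non-deforming"
#' result with no stiffness, never a negative one.
#'
#' @param series A `deformation_series`.
#' @param regime A `regime_window` from [select_bending_regime()], or
#'   `NULL` to select it here.
#' @param temperature Temperature (K); defaults to the series environment.
#' @param kB Boltzmann constant (J/K).
#' @param pixel_dev Axis-measurement deviation (µm) entering the noise
#'   floor; 0 disables it.
#' @param curvature_convention Passed to [build_regressor()].
#' @param ... Passed to [select_bending_regime()] when `regime` is `NULL`.
#' @return Object of class `"kappa_estimate"`: `slope`, `slope_se`,
#'   `intercept_c`, `kappa` (J, `NA` when non-deforming), `kappa_se`,
#'   `r_squared`, `n_points`, `regime`, `status` (`"ok"` or
#'   `"non-deforming"`), `reason`.
#' @export
fit_kappa <- function(series, regime = NULL, temperature = NULL,
                      kB = 1.380649e-23, pixel_dev = 0.29,
                      curvature_convention = c("mean", "sum"), ...) {
  curvature_convention <- match.arg(curvature_convention)
  env <- attr(series, "environment")
  if (is.null(temperature)) {
    temperature <- if (!is.null(env)) env$T else 298
  }
  if (!is.null(env) && !is.null(env$kB)) kB <- env$kB

  if (is.null(regime)) {
    regime <- tryCatch(
      select_bending_regime(series, curvature_convention = curvature_convention, ...),
      error = function(e) e)
    if (inherits(regime, "error")) {
      return(kappa_estimate_failed(series, conditionMessage(regime)))
    }
  }
  xy <- regression_frame(series, curvature_convention)
  sel <- match(regime$indices, xy$indices)
  if (anyNA(sel)) stop("fit_kappa: regime indices not in the regressable set", call. = FALSE)
  x <- xy$x[sel]; y <- xy$y[sel]

  # centered OLS: the slope depends only on x - mean(x), so any additive
  # shift of the regressor (curvature convention, SI prefactor) cannot move
  # it even at roundoff level
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("fit_kappa: degenerate regressor (no spread)", call. = FALSE)
  s <- sum(xc * yc) / sxx
  intercept <- mean(y) - s * mean(x)
  rss <- sum((yc - s * xc)^2)
  tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  se_resid <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_

  # pixel-measurement noise floor on dA/A0, mapped to a slope SE and added
  # in quadrature to the residual-based SE
  ves <- attr(series, "vesicle")
  se_floor <- 0
  if (pixel_dev > 0 && !is.null(ves)) {
    sd_floor <- propagate_pixel_error(ves, pixel_dev) * mean(y)
    se_floor <- sd_floor / sqrt(sum((x - mean(x))^2))
  }
  se_s <- sqrt(se_resid^2 + se_floor^2)

  if (!is.finite(s) || s <= 0) {
    out <- kappa_estimate_failed(series, "non-positive slope in the selected regime")
    out$slope <- s; out$slope_se <- se_s; out$intercept_c <- intercept
    out$r_squared <- r2; out$n_points <- length(x); out$regime <- regime
    return(out)
  }

  kappa <- kB * temperature / (8 * pi * s)
  structure(list(
    slope = s, slope_se = se_s, intercept_c = intercept,
    kappa = kappa, kappa_se = kappa * se_s / s,
    r_squared = r2, n_points = length(x), regime = regime,
    temperature = temperature, kB = kB,
    vesicle_id = if (!is.null(ves)) ves$id else NA_character_,
    status = "ok", reason = NA_character_
  ), class = "kappa_estimate")
}

kappa_estimate_failed <- function(series, reason) {
  ves <- attr(series, "vesicle")
  structure(list(
    slope = NA_real_, slope_se = NA_real_, intercept_c = NA_real_,
    kappa = NA_real_, kappa_se = NA_real_, r_squared = NA_real_,
    n_points = 0L, regime = NULL,
    temperature = NA_real_, kB = NA_real_,
    vesicle_id = if (!is.null(ves)) ves$id else NA_character_,
    status = "non-deforming", reason = reason
  ), class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  if (identical(x$status, "ok")) {
    cat(sprintf(
      "<kappa_estimate> kappa = %.3g +/- %.2g J (slope %.3g, R2 %.3f, %d pts)\n",
      x$kappa, x$kappa_se, x$slope, x$r_squared, x$n_points))
  } else {
    cat(sprintf("<kappa_estimate> %s (%s)\n", x$status, x$reason))
  }
  invisible(x)
}

#' Propagate the axis-measurement deviation to an area uncertainty
#'
#' First-order propagation of an axis-length deviation through the sphere
#' area: a deviation `delta` on a diameter `D` gives a relative area
#' uncertainty `2*delta/D`. With the two-pixel deviation of 0.29 µm and a
#' 41.4 µm vesicle this is the ±1.4% apparent-area uncertainty used as the
#' measurement-noise scale.
#'
#' @param vesicle A [vesicle()] (diameter `2*R0`), or a diameter in µm.
#' @param pixel_dev Axis deviation (µm), >= 0.
#' @return Relative area uncertainty (dimensionless).
#' @export
propagate_pixel_error <- function(vesicle, pixel_dev = 0.29) {
  stopifnot(is.numeric(pixel_dev), length(pixel_dev) == 1L, pixel_dev >= 0)
  D <- if (is.numeric(vesicle)) vesicle else 2 * vesicle$R0
  stopifnot(is.numeric(D), D > 0)
  2 * pixel_dev / D
}

#' Aggregate bending-stiffness estimates across vesicles
#'
#' Arithmetic mean and sample standard deviation (n−1 denominator) of the
#' defined stiffness values; non-deforming vesicles are counted separately,
#' never averaged.
#'
#' @param estimates List of `kappa_estimate` objects.
#' @return List: `kappa_mean` (J), `kappa_sd` (J, `NA` when fewer than two
#'   defined estimates), `n` (defined), `n_non_deforming`.
#' @export
aggregate_kappa <- function(estimates) {
  if (inherits(estimates, "kappa_estimate")) estimates <- list(estimates)
  kap <- vapply(estimates, function(e) {
    if (identical(e$status, "ok")) e$kappa else NA_real_
  }, numeric(1))
  ok <- kap[is.finite(kap)]
  if (length(ok) == 0L) {
    stop("aggregate_kappa: no vesicle produced a defined bending stiffness",
         call. = FALSE)
  }
  list(
    kappa_mean = mean(ok),
    kappa_sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
    n = length(ok),
    n_non_deforming = sum(!is.finite(kap))
  )
}

# Shared: regressable rows of a series -> (x, y, original row indices).
regression_frame <- function(series, curvature_convention = "mean") {
  df <- as.data.frame(series)
  if (!all(c("E0_V_per_m", "a_um", "b_um", "dA_over_A0") %in% names(df))) {
    stop("expected a deformation series with columns E0_V_per_m, a_um, b_um, dA_over_A0",
         call. = FALSE)
  }
  x <- build_regressor(df$E0_V_per_m, df$a_um, df$b_um,
                       curvature_convention = curvature_convention)
  keep <- is.finite(x) & is.finite(df$dA_over_A0)
  if ("regressable" %in% names(df)) keep <- keep & df$regressable
  list(x = x[keep], y = df$dA_over_A0[keep], indices = which(keep))
}
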