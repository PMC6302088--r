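#' Spheroidal vesicle shape
#'
#' A deformed vesicle is modelled as a spheroid with semi-axis `a` along the
#' field (symmetry) axis and transverse semi-axis `b`. The shape is prolate
#' when `a > b` (elongation along the field), a sphere when `a == b`, and
#' oblate when `a < b`.
#'
#' @param a Semi-axis along the field/symmetry axis (µm). Must be > 0.
#' @param b Transverse semi-axis (µm). Must be > 0.
#' @return An object of class `"spheroid"`: a list with elements `a` and `b`.
#' @examples
#' s <- spheroid(2, 1)
#' spheroid_area(s)
#' @export
spheroid <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("spheroid semi-axes must be finite, positive scalars", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "spheroid")
}

#' @export
print.spheroid <- function(x, ...) {
  mode <- if (x$a > x$b) "prolate" else if (x$a < x$b) "oblate" else "sphere"
  cat(sprintf("<spheroid> a = %.6g um, b = %.6g um (%s)\n", x$a, x$b, mode))
  invisible(x)
}

#' Vesicle descriptor
#'
#' Holds the per-vesicle constants of an electrodeformation experiment: the
#' unperturbed radius `R0` (setting the reference area `A0 = 4*pi*R0^2`) and
#' the camera pixel size.
#'
#' @param id Vesicle label.
#' @param R0 Unperturbed radius (µm), > 0.
#' @param pixel_size µm per pixel, > 0 (default 0.145, a 40x phase-contrast
#'   objective scale at which a two-pixel length deviation is 0.29 µm).
#' @return An object of class `"vesicle"`.
#' @export
vesicle <- function(id = "v1", R0, pixel_size = 0.145) {
  stopifnot(is.numeric(R0), length(R0) == 1L, is.finite(R0), R0 > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  structure(list(id = as.character(id), R0 = as.numeric(R0),
                 pixel_size = as.numeric(pixel_size)), class = "vesicle")
}

#' Thermal environment
#'
#' Absolute temperature and the Boltzmann constant entering the
#' bending-regime relation. `kB` defaults to the CODATA exact value.
#'
#' @param T Absolute temperature (K), > 0. Default 298 K (room temperature).
#' @param kB Boltzmann constant (J/K).
#' @return An object of class `"environment_spec"`.
#' @export
environment_spec <- function(T = 298, kB = 1.380649e-23) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T > 0,
            is.numeric(kB), length(kB) == 1L, kB > 0)
  structure(list(T = as.numeric(T), kB = as.numeric(kB)),
            class = "environment_spec")
}

# asin(e)/e and atanh(e)/e with series guards near e = 0, so the closed-form
# areas stay exact and finite as the shape approaches a sphere.
asin_over_x <- function(x2) {
  # x2 = e^2; returns asin(e)/e
  if (x2 < 1e-4) {
    1 + x2 / 6 + 3 * x2^2 / 40 + 15 * x2^3 / 336
  } else {
    e <- sqrt(x2)
    asin(e) / e
  }
}

atanh_over_x <- function(x2) {
  if (x2 < 1e-4) {
    1 + x2 / 3 + x2^2 / 5 + x2^3 / 7
  } else {
    e <- sqrt(x2)
    atanh(e) / e
  }
}

#' Surface area of a spheroid
#'
#' Closed-form surface area of the spheroid with polar semi-axis `a` and
#' equatorial semi-axis `b`, continuous across the sphere (series-guarded
#' eccentricity terms near `a == b`).
#'
#' @param shape A [spheroid()].
#' @return Surface area in µm².
#' @examples
#' spheroid_area(spheroid(10, 10)) # 400 * pi
#' @export
spheroid_area <- function(shape) {
  shape <- as_spheroid(shape)
  a <- shape$a
  b <- shape$b
  if (a >= b) {
    # prolate (or sphere): e^2 = 1 - b^2/a^2
    e2 <- max(0, 1 - (b / a)^2)
    # A = 2 pi b^2 (1 + (a/b) * asin(e)/e)
    2 * pi * b^2 * (1 + (a / b) * asin_over_x(e2))
  } else {
    # oblate: e^2 = 1 - a^2/b^2
    e2 <- 1 - (a / b)^2
    # A = 2 pi b^2 (1 + (1 - e^2) * atanh(e)/e), with (1-e^2) = a^2/b^2
    2 * pi * b^2 * (1 + (a / b)^2 * atanh_over_x(e2))
  }
}

#' Volume of a spheroid
#'
#' @param shape A [spheroid()].
#' @return Volume `(4/3) * pi * a * b^2` in µm³.
#' @export
spheroid_volume <- function(shape) {
  shape <- as_spheroid(shape)
  4 / 3 * pi * shape$a * shape$b^2
}

#' Mean curvature at the pole and at the equator
#'
#' Principal-curvature means under the convention `H = (c1 + c2)/2`. At the
#' pole both principal curvatures equal `a/b^2`; at the equator they are
#' `b/a^2` (meridian) and `1/b` (parallel). For a prolate shape
#' `Hpo - Heq > 0`, the positive quantity entering the bending-regime
#' regressor. Any constant-factor curvature convention only shifts the
#' regressor additively and is absorbed into the fit intercept.
#'
#' @param shape A [spheroid()].
#' @return Curvature in 1/µm.
#' @export
mean_curvature_pole <- function(shape) {
  shape <- as_spheroid(shape)
  shape$a / shape$b^2
}

#' @rdname mean_curvature_pole
#' @export
mean_curvature_equator <- function(shape) {
  shape <- as_spheroid(shape)
  (shape$b / shape$a^2 + 1 / shape$b) / 2
}

#' Apparent area change of a deformed vesicle
#'
#' Relative excess of the spheroid surface area over the unperturbed sphere
#' area `A0 = 4*pi*R0^2`. Zero for the unperturbed sphere; strictly positive
#' for any fixed-volume deformation (the sphere minimizes area).
#'
#' @param shape A [spheroid()].
#' @param vesicle A [vesicle()] (only `R0` is used), or a positive number
#'   taken as `R0` in µm.
#' @return Dimensionless ΔA/A0.
#' @export
area_change <- function(shape, vesicle) {
  R0 <- if (is.numeric(vesicle)) vesicle else vesicle$R0
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0)
  A0 <- 4 * pi * R0^2
  (spheroid_area(shape) - A0) / A0
}

#' Deform a vesicle at fixed volume to a target apparent area change
#'
#' Inverse of [area_change()] under the fixed-volume constraint
#' `a * b^2 = R0^3` (the sucrose interior is osmotically trapped, so the
#' enclosed volume is conserved during deformation). Parametrized by the
#' aspect ratio `t = a/b`: `a = R0 * t^(2/3)`, `b = R0 * t^(-1/3)`; the area
#' change is strictly increasing in `|log t|`, so the root is unique on each
#' branch.
#'
#' @param vesicle A [vesicle()] or a positive number taken as `R0` (µm).
#' @param target_dA Target ΔA/A0, >= 0.
#' @param mode `"prolate"` (default, elongation along the field) or
#'   `"oblate"`.
#' @return A [spheroid()] whose [area_change()] equals `target_dA` to a
#'   relative tolerance of about 1e-10.
#' @export
deform_at_fixed_volume <- function(vesicle, target_dA, mode = c("prolate", "oblate")) {
  mode <- match.arg(mode)
  R0 <- if (is.numeric(vesicle)) vesicle else vesicle$R0
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0)
  if (!is.numeric(target_dA) || length(target_dA) != 1L || !is.finite(target_dA) ||
      target_dA < 0) {
    stop("target_dA must be a finite scalar >= 0", call. = FALSE)
  }
  if (target_dA == 0) {
    return(spheroid(R0, R0))
  }
  shape_of <- function(lt) {
    # lt = log aspect ratio, positive prolate / negative oblate
    t <- exp(if (mode == "prolate") lt else -lt)
    spheroid(R0 * t^(2 / 3), R0 * t^(-1 / 3))
  }
  f <- function(lt) area_change(shape_of(lt), R0) - target_dA
  hi <- 0.5
  while (f(hi) < 0 && hi < 50) hi <- hi * 2
  if (f(hi) < 0) {
    stop(sprintf("deform_at_fixed_volume: no aspect ratio reaches dA/A0 = %g", target_dA),
         call. = FALSE)
  }
  root <- stats::uniroot(f, lower = 0, upper = hi, tol = 1e-14)
  out <- shape_of(root$root)
  resid <- abs(area_change(out, R0) - target_dA)
  # relative tolerance for meaningful targets, absolute floor where the
  # area difference itself is at roundoff scale
  if (resid > 1e-10 * target_dA + 1e-12) {
    stop(sprintf(
      "deform_at_fixed_volume: solver did not converge (target %g, residual %g)",
      target_dA, resid), call. = FALSE)
  }
  out
}

as_spheroid <- function(x) {
  if (inherits(x, "spheroid")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(spheroid(x[[1]], x[[2]]))
  stop("expected a spheroid or a numeric (a, b) pair", call. = FALSE)
}
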