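#' Binarize a phase-contrast frame
#'
#' ImageJ-style global segmentation: Otsu threshold, keep the dark side
#' (sucrose-filled vesicles image darker than the bath), fill interior
#' holes, and drop connected components smaller than `min_area_px`.
#' Deterministic.
#'
#' @param frame An `image_frame` (see [render_vesicle_frame()]) or a numeric
#'   intensity matrix in [0, 1].
#' @param min_area_px Minimum component area kept (px).
#' @param dark_foreground If `TRUE` (default) the below-threshold side is
#'   foreground.
#' @return Integer 0/1 mask matrix of the same size.
#' @export
binarize <- function(frame, min_area_px = 50, dark_foreground = TRUE) {
  img <- frame_intensity(frame)
  if (!all(is.finite(img))) stop("binarize: non-finite intensities", call. = FALSE)
  rng <- range(img)
  if (diff(rng) < 1e-12) {
    stop("binarize: constant frame, no foreground found", call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  mask <- if (dark_foreground) img < thr else img > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(mask)
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) {
    stop("binarize: no component survived the minimum-area filter", call. = FALSE)
  }
  out <- matrix(0L, nrow(img), ncol(img))
  out[labm %in% keep] <- 1L
  out
}

#' Extract the sub-pixel boundary of the largest component
#'
#' Marching-squares contour of the largest connected component at level 0.5,
#' giving an ordered, closed, sub-pixel boundary. Coordinates follow the
#' image convention: 0-based pixel indices, `x` along columns, `y` along
#' rows, origin at the top-left.
#'
#' @param mask 0/1 matrix from [binarize()].
#' @return A `data.frame` with columns `x`, `y` (closed: last point repeats
#'   the first), and attribute `truncated` flagging components touching the
#'   frame edge.
#' @export
extract_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) stop("extract_contour: empty mask", call. = FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comp <- (lab == big) * 1

  nr <- nrow(comp); nc <- ncol(comp)
  touches <- any(comp[1, ] > 0) || any(comp[nr, ] > 0) ||
    any(comp[, 1] > 0) || any(comp[, nc] > 0)
  if (touches) {
    warning("extract_contour: component touches the frame edge (truncated vesicle)")
  }

  # pad with zeros so the contour closes even at the frame edge
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- comp
  # contourLines' x runs over the first index (rows), y over columns
  cl <- grDevices::contourLines(x = seq_len(nr + 2) - 2, y = seq_len(nc + 2) - 2,
                                z = pad, levels = 0.5)
  if (length(cl) == 0L) stop("extract_contour: no contour found", call. = FALSE)
  lens <- vapply(cl, function(c0) length(c0$x), numeric(1))
  c0 <- cl[[which.max(lens)]]
  out <- data.frame(x = c0$y, y = c0$x)  # swap: columns are image x
  attr(out, "truncated") <- touches
  out
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to boundary points by the direct algebraic conic fit
#' constrained to an ellipse (generalized eigenvalue formulation with the
#' 4AC - B^2 = 1 constraint), after centering and scaling the data for
#' numerical conditioning.
#'
#' @param contour A `data.frame`/matrix with columns `x`, `y` (>= 6 points).
#' @return List of class `"ellipse_fit"`: `cx`, `cy` (center), `a_px`
#'   (major semi-axis), `b_px` (minor), `theta` (orientation of the major
#'   axis from +x, counterclockwise, in [0, pi)).
#' @export
fit_ellipse <- function(contour) {
  xy <- as.matrix(as.data.frame(contour)[, c("x", "y")])
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 6) stop("fit_ellipse: need at least 6 points", call. = FALSE)
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  sc <- max(stats::sd(xy[, 1]), stats::sd(xy[, 2]))
  if (!is.finite(sc) || sc < 1e-12) {
    stop("fit_ellipse: degenerate point set", call. = FALSE)
  }
  x <- (xy[, 1] - mx) / sc
  y <- (xy[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T3)) stop("fit_ellipse: degenerate (collinear?) points", call. = FALSE)
  M <- S1 + S2 %*% T3
  # constraint matrix C^-1 * M with C = [[0,0,2],[0,-1,0],[2,0,0]]
  Mc <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(Mc)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) stop("fit_ellipse: no elliptical solution", call. = FALSE)
  a1 <- evec[, ok[1]]
  coef <- c(a1, as.vector(T3 %*% a1))  # A B C D E F in scaled frame

  # un-scale conic: x_s = (x - mx)/sc etc.
  A <- coef[1] / sc^2
  B <- coef[2] / sc^2
  C <- coef[3] / sc^2
  D <- coef[4] / sc - 2 * A * mx - B * my
  E <- coef[5] / sc - 2 * C * my - B * mx
  F <- coef[6] + A * mx^2 + B * mx * my + C * my^2 -
    (coef[4] / sc) * mx - (coef[5] / sc) * my

  den <- 4 * A * C - B^2
  if (den <= 0) stop("fit_ellipse: fitted conic is not an ellipse", call. = FALSE)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  # eigen-decompose the quadratic form [[A, B/2], [B/2, C]]
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  if (any(lam * (-Fc) <= 0)) stop("fit_ellipse: degenerate ellipse", call. = FALSE)
  axes <- sqrt(-Fc / lam)       # one per eigenvalue, sign-safe
  imaj <- which.max(axes)
  major <- axes[imaj]; minor <- axes[-imaj]
  vmaj <- eg$vectors[, imaj]
  theta <- atan2(vmaj[2], vmaj[1]) %% pi

  structure(list(cx = cx, cy = cy, a_px = major, b_px = minor, theta = theta),
            class = "ellipse_fit")
}

#' Segment one frame into a fitted vesicle ellipse
#'
#' Convenience chain: [binarize()] then [extract_contour()] then
#' [fit_ellipse()], optionally followed by sub-pixel refinement of the
#' contour on the intensity image (each boundary point is moved along the
#' ellipse normal to the threshold crossing of the bilinearly interpolated
#' intensity) and a refit. Refinement removes the ~0.1 px quantization bias
#' of the binary mask boundary, the accuracy limit of the axis
#' measurements.
#'
#' @param frame An `image_frame` or intensity matrix.
#' @param min_area_px Passed to [binarize()].
#' @param refine Refine the contour to sub-pixel on the intensity image
#'   (default `TRUE`; falls back to the mask contour if fewer than half the
#'   points bracket the threshold crossing).
#' @return List of class `"segmented_vesicle"`: `ellipse` (an
#'   `ellipse_fit`), `contour`, `area_px` (component pixel count),
#'   `equivalent_diameter_um` (`NA` unless pixel size is known),
#'   `truncated`, `refined`.
#' @export
segment_vesicle <- function(frame, min_area_px = 50, refine = TRUE) {
  img <- frame_intensity(frame)
  mask <- binarize(frame, min_area_px = min_area_px)
  contour <- extract_contour(mask)
  ell <- fit_ellipse(contour)
  refined <- FALSE
  if (refine) {
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    rc <- refine_contour(contour, img, ell, level = thr)
    if (!is.null(rc)) {
      ell2 <- tryCatch(fit_ellipse(rc), error = function(e) NULL)
      if (!is.null(ell2)) {
        contour <- rc
        ell <- ell2
        refined <- TRUE
      }
    }
  }
  ps <- if (inherits(frame, "image_frame")) frame$pixel_size else NA_real_
  area_px <- sum(mask)
  structure(list(
    ellipse = ell, contour = contour, area_px = area_px,
    equivalent_diameter_um = if (is.na(ps)) NA_real_ else
      equivalent_diameter(area_px, ps),
    truncated = isTRUE(attr(contour, "truncated")),
    refined = refined
  ), class = "segmented_vesicle")
}

# Move each contour point along the outward ellipse normal to the sub-pixel
# crossing of `level` in the bilinearly interpolated intensity. Returns NULL
# when fewer than half the points bracket a crossing (non-canonical
# contrast), so callers can fall back to the mask contour.
refine_contour <- function(contour, img, ellipse, level, reach = 2.5) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 8) return(NULL)
  # outward normal of the fitted ellipse at the nearest boundary azimuth
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  xr <- (x - ellipse$cx) * ct + (y - ellipse$cy) * st
  yr <- -(x - ellipse$cx) * st + (y - ellipse$cy) * ct
  nx0 <- xr / ellipse$a_px^2
  ny0 <- yr / ellipse$b_px^2
  nrm <- sqrt(nx0^2 + ny0^2)
  nx0 <- nx0 / nrm; ny0 <- ny0 / nrm
  nx <- nx0 * ct - ny0 * st
  ny <- nx0 * st + ny0 * ct

  offs <- seq(-reach, reach, by = 0.25)
  # intensity profile along the normal, points x offsets
  prof <- vapply(offs, function(s) {
    bilinear_sample(img, x + s * nx, y + s * ny)
  }, numeric(n))

  newx <- rep(NA_real_, n); newy <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- prof[i, ]
    if (anyNA(p)) next
    d <- p - level
    cross <- which(d[-length(d)] <= 0 & d[-1] > 0)
    if (length(cross) == 0L) next
    # crossing nearest the current point
    j <- cross[which.min(abs(offs[cross] + 0.125))]
    s0 <- offs[j] + 0.25 * (-d[j]) / (d[j + 1] - d[j])
    newx[i] <- x[i] + s0 * nx[i]
    newy[i] <- y[i] + s0 * ny[i]
  }
  ok <- is.finite(newx)
  if (mean(ok) < 0.5) return(NULL)
  data.frame(x = newx[ok], y = newy[ok])
}

# Bilinear interpolation of a matrix at image coordinates (x = col, y =
# row), 0-based; NA outside.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- rep(NA_real_, length(x))
  ok <- x0 >= 0 & x0 <= nc - 2 & y0 >= 0 & y0 <= nr - 2
  if (!any(ok)) return(out)
  i00 <- cbind(y0[ok] + 1, x0[ok] + 1)
  i01 <- cbind(y0[ok] + 1, x0[ok] + 2)
  i10 <- cbind(y0[ok] + 2, x0[ok] + 1)
  i11 <- cbind(y0[ok] + 2, x0[ok] + 2)
  out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
    img[i01] * fx[ok] * (1 - fy[ok]) +
    img[i10] * (1 - fx[ok]) * fy[ok] +
    img[i11] * fx[ok] * fy[ok]
  out
}

#' Area-equivalent diameter
#'
#' Diameter of the circle with the same area as the segmented object (the
#' ImageJ convention), or — via `method = "axes"` on an ellipse — the
#' geometric mean of the fitted axes (identical for an exact ellipse).
#'
#' @param x Pixel area (count), a 0/1 mask matrix, or an `ellipse_fit`.
#' @param pixel_size µm per pixel.
#' @param method `"area"` (default) or `"axes"` (ellipse only).
#' @return Diameter in µm.
#' @export
equivalent_diameter <- function(x, pixel_size, method = c("area", "axes")) {
  method <- match.arg(method)
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (inherits(x, "ellipse_fit")) {
    if (method == "axes") return(2 * sqrt(x$a_px * x$b_px) * pixel_size)
    area <- pi * x$a_px * x$b_px
  } else if (is.matrix(x)) {
    area <- sum(x > 0)
  } else {
    area <- as.numeric(x)
  }
  if (!is.finite(area) || area <= 0) stop("equivalent_diameter: non-positive area", call. = FALSE)
  2 * sqrt(area / pi) * pixel_size
}

#' Measure principal axes across an image stack
#'
#' Reproduces the manual measurement chain: every frame is segmented, an
#' ellipse fitted, and the semi-axis along the field axis reported as `a`
#' (transverse as `b`), converted to µm. The unperturbed radius `R0` is the
#' area-equivalent radius of the zero-field frame, so its ΔA/A0 is exactly
#' zero; all other frames' ΔA/A0 follow from the spheroid geometry. Frames
#' whose segmentation fails are excluded and logged in the `dropped`
#' attribute.
#'
#' @param stack An `image_stack` (see [render_series()]), or a list with
#'   `frames`, `E0_V_per_m`, `pixel_size`.
#' @param field_axis `"x"` (default) or `"y"`: image axis of the applied
#'   field.
#' @param min_area_px Passed to [binarize()].
#' @return A `deformation_series` data.frame (same dialect as
#'   [generate_deformation_series()]), with attribute `dropped` listing
#'   excluded frames and reasons.
#' @export
measure_axes <- function(stack, field_axis = c("x", "y"), min_area_px = 50) {
  field_axis <- match.arg(field_axis)
  frames <- stack$frames
  E0 <- stack$E0_V_per_m
  ps <- stack$pixel_size
  freq <- if (!is.null(stack$frequency_Hz)) stack$frequency_Hz[1] else NA_real_
  stopifnot(length(frames) == length(E0), is.numeric(ps), ps > 0)
  if (!any(E0 <= 0)) {
    stop("measure_axes: no zero-field frame, cannot set the reference radius R0",
         call. = FALSE)
  }

  n <- length(frames)
  a_um <- b_um <- rep(NA_real_, n)
  dropped <- character(0)
  for (i in seq_len(n)) {
    seg <- tryCatch(segment_vesicle(frames[[i]], min_area_px = min_area_px),
                    error = function(e) e)
    if (inherits(seg, "error")) {
      dropped <- c(dropped, sprintf("frame %d (E0 = %g V/m): %s", i, E0[i],
                                    conditionMessage(seg)))
      next
    }
    ell <- seg$ellipse
    # semi-axis along the field direction
    along_major <- if (field_axis == "x") {
      abs(cos(ell$theta)) >= abs(sin(ell$theta))
    } else {
      abs(sin(ell$theta)) >= abs(cos(ell$theta))
    }
    a_um[i] <- (if (along_major) ell$a_px else ell$b_px) * ps
    b_um[i] <- (if (along_major) ell$b_px else ell$a_px) * ps
  }

  iz <- which(E0 <= 0 & !is.na(a_um))
  if (length(iz) == 0L) {
    stop("measure_axes: zero-field frame failed to segment", call. = FALSE)
  }
  iz <- iz[1]
  # area-equivalent radius of the zero-field shape -> its dA/A0 is exactly 0
  R0 <- sqrt(spheroid_area(spheroid(a_um[iz], b_um[iz])) / (4 * pi))
  ves <- vesicle(id = if (!is.null(stack$vesicle)) stack$vesicle$id else "measured",
                 R0 = R0, pixel_size = ps)

  keep <- which(!is.na(a_um))
  dA <- vapply(keep, function(i) {
    max(area_change(spheroid(a_um[i], b_um[i]), R0), 0)
  }, numeric(1))
  out <- data.frame(
    vesicle_id = ves$id,
    E0_V_per_m = E0[keep],
    frequency_Hz = freq,
    a_um = a_um[keep],
    b_um = b_um[keep],
    dA_over_A0 = dA,
    regressable = E0[keep] > 0 & a_um[keep] > b_um[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$E0_V_per_m), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            vesicle = ves,
            environment = environment_spec(),
            dropped = dropped,
            class = c("deformation_series", "data.frame"))
}

#' Vesicle size distribution
#'
#' Histogram plus summary statistics of a diameter sample. Bins are closed
#' on the left and open on the right; the last bin is closed on both sides,
#' so every diameter is counted exactly once.
#'
#' @param diameters Numeric vector of diameters (µm), n >= 1.
#' @param bin_width Bin width (µm), used when `edges` is `NULL`; default
#'   5 µm.
#' @param edges Explicit bin edges (overrides `bin_width`).
#' @return Object of class `"size_distribution"`: `diameters`, `bin_edges`,
#'   `counts`, `mean`, `sd`, `n`.
#' @export
size_distribution <- function(diameters, bin_width = 5, edges = NULL) {
  d <- as.numeric(diameters)
  d <- d[is.finite(d)]
  if (length(d) < 1L) stop("size_distribution: need at least one diameter", call. = FALSE)
  if (is.null(edges)) {
    lo <- floor(min(d) / bin_width) * bin_width
    hi <- ceiling(max(d) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi, by = bin_width)
  }
  edges <- sort(unique(as.numeric(edges)))
  if (min(d) < edges[1] || max(d) > edges[length(edges)]) {
    stop("size_distribution: diameters outside the bin range", call. = FALSE)
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(
    diameters = d,
    bin_edges = edges,
    counts = counts,
    mean = mean(d),
    sd = if (length(d) > 1) stats::sd(d) else NA_real_,
    n = length(d)
  ), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> n = %d, mean = %.2f um, sd = %s um, %d bins\n",
              x$n, x$mean, if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
              length(x$counts)))
  invisible(x)
}

frame_intensity <- function(frame) {
  if (inherits(frame, "image_frame")) return(frame$intensity)
  if (is.matrix(frame)) return(frame)
  stop("expected an image_frame or an intensity matrix", call. = FALSE)
}
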