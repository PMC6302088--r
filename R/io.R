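#' Write / read a deformation series as CSV
#'
#' The on-disk dialect has columns `vesicle_id`, `E0_V_per_m`,
#' `frequency_Hz`, `a_um`, `b_um`, `dA_over_A0`, `regressable`, preceded by
#' `#`-comment header lines recording the vesicle radius, pixel size,
#' temperature, and the generator seed, so every output is traceable to its
#' provenance.
#'
#' @param series A `deformation_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "deformation_series"))
  ves <- attr(series, "vesicle")
  env <- attr(series, "environment")
  truth <- attr(series, "truth")
  hdr <- c(
    sprintf("# vesicle_id: %s", ves$id),
    sprintf("# R0_um: %.10g", ves$R0),
    sprintf("# pixel_size_um: %.10g", ves$pixel_size),
    sprintf("# temperature_K: %.10g", env$T),
    if (!is.null(truth)) sprintf("# seed: %d", truth$seed)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param id Vesicle id override (default: from the file header).
#' @return `read_series_csv()`: a `deformation_series`.
#' @export
read_series_csv <- function(path, id = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE)
  df$regressable <- as.logical(df$regressable)
  R0 <- suppressWarnings(as.numeric(getval("R0_um")))
  ps <- suppressWarnings(as.numeric(getval("pixel_size_um")))
  Tk <- suppressWarnings(as.numeric(getval("temperature_K")))
  ves <- vesicle(id = if (!is.null(id)) id else
                   if (!is.na(getval("vesicle_id"))) getval("vesicle_id") else "v1",
                 R0 = if (is.finite(R0)) R0 else
                   max((df$a_um * df$b_um^2)^(1 / 3)),
                 pixel_size = if (is.finite(ps)) ps else 0.145)
  structure(df,
            vesicle = ves,
            environment = environment_spec(T = if (is.finite(Tk)) Tk else 298),
            class = c("deformation_series", "data.frame"))
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are written as 16-bit grayscale pages; the field metadata, pixel
#' size, and ground-truth ellipses go to a JSON sidecar (`<path>.json`).
#'
#' @param stack An `image_stack` (see [render_series()]).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(stack$frames, frame_intensity)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  sidecar <- list(
    pixel_size_um = stack$pixel_size,
    E0_V_per_m = stack$E0_V_per_m,
    frequency_Hz = stack$frequency_Hz,
    vesicle_id = if (!is.null(stack$vesicle)) stack$vesicle$id else "v1",
    truth = lapply(stack$frames, function(f) f$truth)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("read_stack_tiff: missing sidecar ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  ps <- meta$pixel_size_um
  frames <- lapply(seq_along(pages), function(i) {
    tr <- if (!is.null(meta$truth)) as.list(meta$truth[i, , drop = TRUE]) else NULL
    structure(list(intensity = pages[[i]], pixel_size = ps, truth = tr),
              class = "image_frame")
  })
  structure(list(frames = frames,
                 E0_V_per_m = as.numeric(meta$E0_V_per_m),
                 frequency_Hz = meta$frequency_Hz,
                 pixel_size = ps,
                 vesicle = vesicle(id = meta$vesicle_id,
                                   R0 = 1, pixel_size = ps)),
            class = "image_stack")
}

#' Write a bending-stiffness table as CSV
#'
#' One row per vesicle: `vesicle_id`, `kappa_J`, `kappa_se_J`, `slope`,
#' `intercept`, `r2`, `regime_lo`, `regime_hi`, `n_points`, `status`.
#'
#' @param estimates List of `kappa_estimate` objects.
#' @param path Output CSV path (`NULL` returns the data.frame only).
#' @param seed Optional seed recorded in a header comment.
#' @return The table, invisibly if written.
#' @export
write_kappa_table <- function(estimates, path = NULL, seed = NULL) {
  if (inherits(estimates, "kappa_estimate")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(
      vesicle_id = e$vesicle_id,
      kappa_J = e$kappa,
      kappa_se_J = e$kappa_se,
      slope = e$slope,
      intercept = e$intercept_c,
      r2 = e$r_squared,
      regime_lo = if (!is.null(e$regime)) e$regime$lo else NA_integer_,
      regime_hi = if (!is.null(e$regime)) e$regime$hi else NA_integer_,
      n_points = e$n_points,
      status = e$status,
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
    utils::write.csv(tab, con, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
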