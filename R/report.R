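#' Run the simulate -> fit -> summarize pipeline
#'
#' End-to-end driver: simulates `n_vesicles` electrodeformation series with
#' radii drawn from the vesicle population, fits each series' bending
#' stiffness, writes the series CSVs, the stiffness table, the population
#' size distribution, a run log, and a JSON manifest recording the full
#' configuration and seed. Deterministic given the seed: rerunning the same
#' configuration reproduces every output byte for byte.
#'
#' @param config A named list, or a path to a YAML/JSON configuration file.
#'   Recognized entries (all optional): `n_vesicles`, `seed`, `out_dir`,
#'   `temperature`, `kappa_true`, `noise_sd_dA`, `noise_model`,
#'   `population` (list: `n`, `median_um`, `sigma_log`, `min_um`, `max_um`),
#'   `bin_width_um`, `render` (logical: run the image route instead of the
#'   tabular route), plus overrides forwarded to [synthetic_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @param seed Integer seed (overrides `config$seed`).
#' @return List: `kappa_table` (data.frame), `summary` (from
#'   [aggregate_kappa()]), `sizes` (a `size_distribution`), `paths` of the
#'   written artifacts, `log` (character).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  config <- load_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  cfg <- utils::modifyList(list(
    n_vesicles = 1L, seed = 1L, out_dir = tempfile("guvkappa_run_"),
    temperature = 298, kappa_true = 4.5e-19,
    noise_sd_dA = 0.014, noise_model = "relative",
    population = list(n = 700, median_um = 25, sigma_log = 0.4,
                      min_um = 10, max_um = 60),
    bin_width_um = 5, render = FALSE
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("guvkappa: ", msg)
  }

  seed <- as.integer(cfg$seed)
  note("run seed %d, %d vesicle(s), out_dir %s", seed, cfg$n_vesicles, cfg$out_dir)

  pop <- do.call(generate_population,
                 c(cfg$population, list(seed = seed + 1000L)))
  sizes <- size_distribution(pop, bin_width = cfg$bin_width_um)
  R0s <- generate_population(cfg$n_vesicles,
                             median_um = cfg$population$median_um,
                             sigma_log = cfg$population$sigma_log,
                             min_um = cfg$population$min_um,
                             max_um = cfg$population$max_um,
                             seed = seed + 2000L) / 2

  estimates <- vector("list", cfg$n_vesicles)
  series_paths <- character(cfg$n_vesicles)
  for (i in seq_len(cfg$n_vesicles)) {
    sc <- synthetic_config(
      kappa_true = cfg$kappa_true, T = cfg$temperature,
      noise_sd_dA = cfg$noise_sd_dA, noise_model = cfg$noise_model,
      R0 = R0s[i], seed = seed + i)
    ves <- vesicle(id = sprintf("v%03d", i), R0 = R0s[i],
                   pixel_size = sc$pixel_size)
    stage <- sprintf("vesicle %s", ves$id)
    series <- tryCatch(generate_deformation_series(sc, ves),
                       error = function(e) e)
    if (inherits(series, "error")) {
      stop(sprintf("run_pipeline [simulate, %s]: %s", stage,
                   conditionMessage(series)), call. = FALSE)
    }
    if (isTRUE(cfg$render)) {
      stack <- render_series(series, seed = seed + 100L * i)
      tif <- file.path(cfg$out_dir, sprintf("stack_%s.tif", ves$id))
      write_stack_tiff(stack, tif)
      series <- measure_axes(stack)
      for (d in attr(series, "dropped")) note("[segment, %s] dropped %s", stage, d)
    }
    series_paths[i] <- file.path(cfg$out_dir, sprintf("series_%s.csv", ves$id))
    write_series_csv(series, series_paths[i])
    est <- fit_kappa(series, temperature = cfg$temperature)
    if (!identical(est$status, "ok")) {
      note("[fit, %s] %s: %s", stage, est$status, est$reason)
    }
    estimates[[i]] <- est
  }

  kap_path <- file.path(cfg$out_dir, "kappa.csv")
  tab <- write_kappa_table(estimates, kap_path, seed = seed)
  summ <- tryCatch(aggregate_kappa(estimates), error = function(e) {
    note("[aggregate] %s", conditionMessage(e))
    NULL
  })

  size_path <- file.path(cfg$out_dir, "size_distribution.csv")
  utils::write.csv(data.frame(
    bin_lo = sizes$bin_edges[-length(sizes$bin_edges)],
    bin_hi = sizes$bin_edges[-1],
    count = sizes$counts), size_path, row.names = FALSE)

  manifest <- list(package = "guvkappa",
                   version = as.character(utils::packageVersion("guvkappa")),
                   seed = seed, config = cfg[setdiff(names(cfg), "out_dir")],
                   summary = summ)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_path <- file.path(cfg$out_dir, "run.log")
  writeLines(log_lines, log_path)

  list(kappa_table = tab, summary = summ, sizes = sizes,
       paths = list(series = series_paths, kappa = kap_path,
                    sizes = size_path, manifest = man_path, log = log_path),
       log = log_lines)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    }
    return(yaml::read_yaml(config))
  }
  stopifnot(is.list(config))
  config
}

#' Summarize replicate contact-angle measurements
#'
#' Per-film mean and sample standard deviation of replicate contact-angle
#' readings, the reduction used for wettability characterization of
#' nanotube films.
#'
#' @param value Numeric measurements (degrees).
#' @param film Film label per measurement (recycled if scalar).
#' @return data.frame: `film`, `mean`, `sd`, `n` (one row per film).
#' @export
summarize_contact_angles <- function(value, film = "film") {
  stopifnot(is.numeric(value), length(value) >= 1L)
  film <- rep_len(as.character(film), length(value))
  out <- do.call(rbind, lapply(split(value, film), function(v) {
    data.frame(mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  out <- data.frame(film = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$film), , drop = FALSE]
}

#' Summarize length/diameter replicate measurements
#'
#' Mean and sample standard deviation of a replicate set (e.g. nanotube
#' lengths or diameters measured from micrographs). Requires at least two
#' values for a defined standard deviation.
#'
#' @param measurements Numeric vector, n >= 2.
#' @return List: `mean`, `sd`, `n`.
#' @export
summarize_lengths <- function(measurements) {
  x <- as.numeric(measurements)
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    stop("summarize_lengths: need at least two measurements", call. = FALSE)
  }
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}
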