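# File formats: spectra matrix CSV (first row wavelengths, first column
# sample id), trajectory CSV, event-log CSV, model JSON, run manifests.
# All UTF-8, dot decimal separator, full precision round trips.

#' Read / write a spectra matrix CSV
#'
#' Format: header `id, <wl1>, <wl2>, ...` with strictly increasing
#' wavelengths (nm); one row per sample. Values round-trip at full
#' double precision.
#'
#' @param path file path.
#' @return `read_spectra_csv`: numeric matrix (samples x wavelengths)
#'   with attribute `wavelengths` and row names from the id column.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_config("empty spectra file: ", path)
  split_row <- function(l) strsplit(l, ",", fixed = TRUE)[[1L]]
  hdr <- split_row(lines[1L])
  grid <- suppressWarnings(as.numeric(hdr[-1L]))
  if (any(is.na(grid))) stop_config("non-numeric wavelength in header")
  if (is.unsorted(grid, strictly = TRUE))
    stop_config("wavelength header is not strictly increasing")
  p <- length(grid)
  n <- length(lines) - 1L
  if (n == 0L) stop_config("spectra file has a header but no samples")
  X <- matrix(NA_real_, n, p)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- split_row(lines[i + 1L])
    if (length(f) != p + 1L)
      stop_config("ragged row ", i, ": expected ", p + 1L, " fields, got ",
                  length(f))
    ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (any(is.na(v))) stop_config("non-numeric absorbance in row ", i)
    X[i, ] <- v
  }
  rownames(X) <- ids
  attr(X, "wavelengths") <- grid
  X
}

#' @rdname read_spectra_csv
#' @param X spectra matrix with a `wavelengths` attribute (or
#'   `wavelengths` supplied).
#' @param wavelengths optional grid override.
#' @export
write_spectra_csv <- function(X, path, wavelengths = NULL) {
  grid <- wavelengths %||% attr(X, "wavelengths")
  if (is.null(grid)) stop_config("no wavelengths attribute on X")
  X <- as.matrix(X)
  if (length(grid) != ncol(X)) stop_config("grid length != ncol(X)")
  ids <- rownames(X) %||% paste0("s", seq_len(nrow(X)))
  fmt <- function(v) format(v, digits = 17, trim = TRUE,
                            scientific = FALSE, nsmall = 0)
  lines <- c(paste(c("id", fmt(grid)), collapse = ","),
             vapply(seq_len(nrow(X)), function(i)
               paste(c(ids[i], format(X[i, ], digits = 17, trim = TRUE)),
                     collapse = ","), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a fermentation trajectory CSV
#'
#' Columns `time_h, glucose_gL, lactate_gL, acetate_gL, biomass_gL,
#' volume_L, event` (plus predicted-concentration columns for
#' closed-loop trajectories).
#'
#' @param traj a `fermentation_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(tr, class = c("fermentation_trajectory", "data.frame"))
}

#' Write an event log CSV
#' @param events an `event_log` data frame from [run_closed_loop()].
#' @param path file path.
#' @export
write_eventlog_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize / restore a calibration model as JSON
#'
#' Structured-text round trip at full double precision: method,
#' pretreatment, grid, channel mask, coefficients, PLS loadings, factor
#' count and training statistics all survive exactly.
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  x <- model
  x$instrument <- unclass(x$instrument)
  x$pretreatment <- unclass(x$pretreatment)
  x$training_stats <- unclass(x$training_stats)
  x$validation <- if (!is.null(x$validation)) unclass(x$validation)
  x$screen <- NULL   # large diagnostics stay in memory only
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE,
                       digits = I(17),  # 17 significant digits: exact
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$instrument <- structure(x$instrument, class = "instrument_spec")
  x$pretreatment <- structure(
    list(kind = x$pretreatment$kind,
         segment = as.integer(x$pretreatment$segment),
         gap = as.integer(x$pretreatment$gap)),
    class = "pretreatment_spec")
  if (!is.null(x$training_stats))
    x$training_stats <- structure(x$training_stats,
                                  class = "validation_stats")
  if (!is.null(x$validation))
    x$validation <- structure(x$validation, class = "validation_stats")
  x$used_idx <- as.integer(x$used_idx)
  structure(x, class = "calibration_model")
}

#' Read / write a study configuration file
#'
#' One JSON document per study: organism, instrument, method, set
#' sizes, assay noise standard deviations, hydrodynamics and seed.
#'
#' @param path file path.
#' @return a [study_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  org <- switch(x$organism %||% "homolactic",
                homolactic = organism_homolactic(),
                heterolactic_cluster = organism_heterolactic("cluster"),
                heterolactic_rod = organism_heterolactic("rod"),
                heterolactic_sphere = organism_heterolactic("sphere"),
                stop_config("unknown organism: ", x$organism))
  instr <- switch(x$instrument %||% "filter19",
                  filter19 = instrument_filter19(),
                  fullspectrum = instrument_fullspectrum(),
                  probe = instrument_probe(),
                  stop_config("unknown instrument: ", x$instrument))
  nz <- x$noise %||% list()
  noise <- assay_noise_model(nz$sd_glucose %||% 1.0, nz$sd_lactate %||% 1.0,
                             nz$sd_acetate %||% 1.0, nz$sd_biomass %||% 0.8)
  hy <- x$hydro %||% list()
  study_config(org, instr, method = x$method %||% "MLR",
               n_calibration = x$n_calibration %||% 45,
               n_validation = x$n_validation %||% 30,
               noise = noise,
               hydro = hydrodynamic_state(hy$stirring %||% 120,
                                          hy$airflow %||% 0),
               max_factors = x$max_factors %||% 12,
               seed = as.integer(x$seed %||% 1L))
}

#' @rdname read_config
#' @param config a [study_config()].
#' @export
write_config <- function(config, path) {
  org <- switch(config$organism$name,
                homolactic_LAB = "homolactic",
                heterolactic_cluster = "heterolactic_cluster",
                heterolactic_rod = "heterolactic_rod",
                heterolactic_sphere = "heterolactic_sphere",
                config$organism$name)
  x <- list(organism = org, instrument = config$instrument$geometry,
            method = config$method,
            n_calibration = config$n_calibration,
            n_validation = config$n_validation,
            noise = config$noise[c("sd_glucose", "sd_lactate",
                                   "sd_acetate", "sd_biomass")],
            hydro = list(stirring = config$hydro$stirring,
                         airflow = config$hydro$airflow),
            max_factors = config$max_factors, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run records a manifest next to its outputs: a hash of the
#' effective configuration, the stage seeds used, the artifact paths and
#' the package version. Re-running with an identical manifest input
#' reproduces the outputs bitwise.
#'
#' @param config the effective [study_config()] (or any serializable
#'   config list).
#' @param outputs character vector of artifact paths.
#' @param path manifest path.
#' @export
write_manifest <- function(config, outputs, path) {
  cfg_json <- jsonlite::toJSON(
    if (inherits(config, "study_config")) {
      tmp <- tempfile(); on.exit(unlink(tmp)); write_config(config, tmp)
      jsonlite::read_json(tmp)
    } else config,
    auto_unbox = TRUE, digits = NA)
  seed <- if (inherits(config, "study_config")) config$seed
          else config$seed %||% NA
  man <- list(
    config_hash = fnv1a32(as.character(cfg_json)),
    seed = seed,
    stage_seeds = if (!is.na(seed %||% NA))
      lapply(stats::setNames(nm = c("calibration-design",
                                    "calibration-spectra",
                                    "calibration-assay", "validation")),
             function(s) seed_split(seed, s)) else NULL,
    outputs = as.list(outputs),
    package_version = as.character(utils::packageVersion("nirferm")))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
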