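#' Study configuration
#'
#' Bundles everything one calibration study needs: organism, instrument,
#' regression route, set sizes, assay noise and the root seed from which
#' all stage seeds are derived.
#'
#' @param organism an [organism_profile()].
#' @param instrument an [instrument_spec()].
#' @param method `"MLR"` or `"PLS"`.
#' @param n_calibration,n_validation set sizes.
#' @param noise an [assay_noise_model()] (its `seed` field is ignored;
#'   stage seeds come from `seed`).
#' @param hydro a [hydrodynamic_state()] held constant during
#'   calibration runs.
#' @param pretreatment a [pretreatment_spec()]; the PLS route defaults
#'   to the Norris second derivative, the MLR route to none.
#' @param max_factors upper bound for PRESS factor selection (PLS).
#' @param seed integer root seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(organism, instrument, method = c("MLR", "PLS"),
                         n_calibration, n_validation = 30,
                         noise = assay_noise_model(),
                         hydro = hydrodynamic_state(),
                         pretreatment = NULL, max_factors = 12,
                         seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(organism, "organism_profile"),
            inherits(instrument, "instrument_spec"),
            inherits(noise, "assay_noise_model"),
            inherits(hydro, "hydrodynamic_state"))
  pretreatment <- pretreatment %||%
    if (method == "PLS") pretreatment_spec("norris_d2")
    else pretreatment_spec("none")
  structure(list(organism = organism, instrument = instrument,
                 method = method, n_calibration = as.integer(n_calibration),
                 n_validation = as.integer(n_validation), noise = noise,
                 hydro = hydro, pretreatment = pretreatment,
                 max_factors = as.integer(max_factors),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Default on-line homolactic study (45 calibration + 30 validation, MLR
#' on the 19-filter analyzer)
#' @param seed root seed.
#' @return a [study_config()].
#' @export
study_homolactic <- function(seed = 1L) {
  study_config(organism_homolactic(), instrument_filter19(),
               method = "MLR", n_calibration = 45, n_validation = 30,
               hydro = hydrodynamic_state(stirring = 120, airflow = 0),
               seed = seed)
}

#' Default in-line heterolactic study (80 calibration + 30 validation,
#' Norris-d2 + PLS on the immersion probe)
#' @param shape organism shape, see [organism_heterolactic()].
#' @param seed root seed.
#' @return a [study_config()].
#' @export
study_heterolactic <- function(shape = "cluster", seed = 1L) {
  study_config(organism_heterolactic(shape), instrument_probe(),
               method = "PLS", n_calibration = 80, n_validation = 30,
               hydro = hydrodynamic_state(stirring = 400, airflow = 0.3),
               seed = seed)
}

# stage-seeded noise model from a config
config_noise <- function(config, stage) {
  n <- config$noise
  assay_noise_model(n$sd_glucose, n$sd_lactate, n$sd_acetate, n$sd_biomass,
                    seed = seed_split(config$seed, stage))
}

# generate the (states, spectra, assays) triple for one stage label;
# deterministic in (config, stage)
study_dataset <- function(config, stage = "calibration",
                          n = config$n_calibration) {
  states <- design_calibration_states(
    n, config$organism, seed = seed_split(config$seed, paste0(stage, "-design")))
  X <- generate_spectra_matrix(states, config$instrument, config$hydro,
                               config$organism,
                               seed = seed_split(config$seed,
                                                 paste0(stage, "-spectra")))
  Y <- assay_states(states, config_noise(config, paste0(stage, "-assay")))
  list(states = states, X = X, Y = Y)
}

chromophore_hash <- function(lib) {
  fnv1a32(paste(format(unlist(lib), digits = 12), collapse = ","))
}

#' Build and validate one calibration model
#'
#' The full study workflow for one analyte: design calibration states
#' from jittered batch trajectories, generate spectra and noisy
#' reference assays, pretreat (PLS route), screen outliers by
#' PCA/Mahalanobis distance (PLS route), mask saturated channels, fit
#' (with LOO-PRESS factor selection for PLS), then validate on a fresh
#' external set of `n_validation` samples.
#'
#' @param config a [study_config()].
#' @param analyte `"glucose"`, `"lactate"`, `"acetate"` or `"biomass"`.
#' @return a `calibration_model` with elements `training_stats`,
#'   `validation` (a `validation_stats` on the external set, including
#'   `paired_test`), `screen`, and `press` (PLS route).
#' @export
build_calibration <- function(config, analyte = "glucose") {
  stopifnot(inherits(config, "study_config"))
  ds <- study_dataset(config, "calibration")
  y <- ds$Y[, analyte]
  grid <- attr(ds$X, "wavelengths")
  sat_any <- apply(attr(ds$X, "saturated"), 2L, any)
  log <- list(n_designed = nrow(ds$states),
              n_saturated_channels = sum(sat_any))
  if (config$method == "MLR") {
    used <- which(!sat_any)
    model <- fit_mlr(ds$X[, used, drop = FALSE], y, analyte = analyte,
                     wavelengths = grid[used])
    model$input_wavelengths <- grid
    model$used_idx <- used
    screen <- NULL
    press <- NULL
  } else {
    Z <- norris_second_derivative(ds$X, config$pretreatment,
                                  wavelengths = grid)
    screen <- pca_mahalanobis_screen(Z)
    n_out <- length(screen$outliers)
    if (n_out > 0.2 * nrow(Z))
      stop("screening flagged ", n_out, " of ", nrow(Z),
           " samples (> 20%): calibration design is unsound")
    d2_idx <- attr(Z, "index")
    bad_out <- d2_channels_touching(which(sat_any), ncol(ds$X),
                                    config$pretreatment)
    keep_cols <- which(!(d2_idx %in% bad_out))
    Zi <- Z[screen$inliers, keep_cols, drop = FALSE]
    yi <- y[screen$inliers]
    maxf <- min(config$max_factors, nrow(Zi) - 2L, ncol(Zi))
    press <- press_select(Zi, yi, max_factors = maxf)
    model <- fit_pls(Zi, yi, n_factors = press$n_factors,
                     analyte = analyte,
                     wavelengths = attr(Z, "wavelengths")[keep_cols])
    model$input_wavelengths <- grid
    model$used_idx <- keep_cols
    model$pretreatment <- config$pretreatment
    log$n_outliers <- n_out
    log$n_factors <- model$n_factors
  }
  model$organism <- config$organism$name
  model$chromophore_id <- chromophore_hash(config$organism$chromophores)
  model$instrument <- config$instrument
  model$scatter_coefficient <- config$organism$scatter_coefficient
  model$noise <- config$noise[c("sd_glucose", "sd_lactate", "sd_acetate",
                                "sd_biomass")]
  model$screen <- screen
  model$press <- press
  model$log <- log
  model$validation <- external_validation(model, config,
                                          n = config$n_validation,
                                          seed = seed_split(config$seed,
                                                            "validation"))
  model
}

#' Build a calibration that passes the deployment gate
#'
#' Calibrations are only deployed for closed-loop control after their
#' external validation shows no significant NIR-vs-lab difference in a
#' paired Student's t test at the 1% level. A model failing the gate is
#' discarded and rebuilt from a freshly collected calibration + validation
#' campaign (a derived seed); after `max_attempts` failures the last
#' model is returned with a warning.
#'
#' @param config a [study_config()].
#' @param analyte analyte label.
#' @param alpha significance level of the paired-test gate (default 0.01).
#' @param max_attempts maximum calibration campaigns.
#' @return a `calibration_model` whose `validation$paired_test$p` exceeds
#'   `alpha` (unless the attempt budget ran out); the attempt count is in
#'   `$log$attempts`.
#' @export
build_validated_calibration <- function(config, analyte = "glucose",
                                        alpha = 0.01, max_attempts = 5) {
  cfg <- config
  for (k in seq_len(max_attempts)) {
    model <- build_calibration(cfg, analyte)
    model$log$attempts <- k
    if (model$validation$paired_test$p > alpha) return(model)
    cfg$seed <- seed_split(config$seed, paste0("recalibration-", k))
  }
  warning("no ", analyte, " calibration passed the paired-test gate in ",
          max_attempts, " attempts; returning the last one", call. = FALSE)
  model
}

#' Externally validate a calibration model
#'
#' Generates a fresh set of states, spectra and reference assays that
#' the model has never seen, predicts, and reports the accuracy suite
#' plus a paired NIR-vs-lab Student's t test.
#'
#' @param model a `calibration_model` from [build_calibration()].
#' @param config the [study_config()] (supplies organism, instrument,
#'   hydrodynamics and noise).
#' @param n validation set size (>= 10).
#' @param seed seed of the validation stage.
#' @return a `validation_stats` with extra fields `paired_test` and
#'   `seed`.
#' @export
external_validation <- function(model, config, n = 30, seed = 2L) {
  if (n < 10) stop_config("validation needs n >= 10")
  if (!identical(config$instrument$geometry, model$instrument$geometry))
    stop_config("instrument mismatch between model and config")
  cfg <- config
  cfg$seed <- as.integer(seed)
  ds <- study_dataset(cfg, "external", n = n)
  pred <- predict(model, ds$X)
  ref <- ds$Y[, model$analyte]
  st <- calibration_stats(pred, ref, df_model = 0)
  st$paired_test <- paired_nir_lab_test(pred, ref)
  st$seed <- seed
  st
}

#' Transfer a calibration model to another organism
#'
#' Applies an existing model, unchanged, to broths of a different
#' organism profile and reports external-validation statistics on
#' `n_val` fresh samples. The transfer premise is that both organisms
#' share the chromophore library (no shape-specific spectral features);
#' profiles with no components in common are refused, and a library
#' whose bands differ from the model's raises a warning (the documented
#' failure mode: transfer degrades).
#'
#' @param model a `calibration_model`.
#' @param target the target [organism_profile()].
#' @param n_val validation samples (20 in the original workflow).
#' @param seed integer seed.
#' @param hydro hydrodynamics during the target runs.
#' @return a `validation_stats` (see [external_validation()]).
#' @export
transfer_model <- function(model, target, n_val = 20, seed = 3L,
                           hydro = hydrodynamic_state(400, 0.3)) {
  stopifnot(inherits(target, "organism_profile"))
  shared <- intersect(names(target$chromophores),
                      c("glucose", "lactate", "acetate",
                        "biomass_chromophore", "water"))
  if (length(shared) == 0L)
    stop_config("target organism shares no chromophores with the model: ",
                "transfer premise violated")
  if (!identical(chromophore_hash(target$chromophores),
                 model$chromophore_id))
    warning("target chromophore library differs from the model's; ",
            "expect degraded transfer accuracy", call. = FALSE)
  noise <- do.call(assay_noise_model,
                   c(model$noise, list(seed = seed_split(seed,
                                                         "transfer-assay"))))
  cfg <- study_config(target, model$instrument, method = model$method,
                      n_calibration = n_val, n_validation = n_val,
                      noise = noise, hydro = hydro,
                      pretreatment = model$pretreatment,
                      seed = as.integer(seed))
  ds <- study_dataset(cfg, "transfer", n = n_val)
  pred <- predict(model, ds$X)
  ref <- ds$Y[, model$analyte]
  st <- calibration_stats(pred, ref, df_model = 0)
  st$paired_test <- paired_nir_lab_test(pred, ref)
  st$seed <- seed
  st$target <- target$name
  st
}

#' Mean-spectra discrimination test
#'
#' Computes the difference of the mean spectra of two sets and compares
#' it, wavelength by wavelength, with a +/- 3 pooled-standard-error
#' noise band. The sets are "indistinguishable" iff the difference curve
#' stays inside the band everywhere.
#'
#' @param setA,setB spectra matrices (>= 20 rows each) on one grid.
#' @return list with `difference` (curve), `band` (3 x pooled SE),
#'   `max_abs`, `wavelength_at_max`, `verdict` (`"indistinguishable"` or
#'   `"distinguishable"`).
#' @export
discriminate_mean_spectra <- function(setA, setB) {
  A <- as.matrix(setA); B <- as.matrix(setB)
  if (nrow(A) < 20 || nrow(B) < 20)
    stop_config("each set needs at least 20 spectra")
  ga <- attr(setA, "wavelengths"); gb <- attr(setB, "wavelengths")
  if (ncol(A) != ncol(B) ||
      (!is.null(ga) && !is.null(gb) &&
       !isTRUE(all.equal(as.numeric(ga), as.numeric(gb)))))
    stop_config("wavelength grid mismatch between the two sets")
  diff <- colMeans(A) - colMeans(B)
  se <- sqrt(apply(A, 2L, stats::var) / nrow(A) +
               apply(B, 2L, stats::var) / nrow(B))
  band <- 3 * se
  inside <- abs(diff) <= band + .Machine$double.eps
  i_max <- which.max(abs(diff) - band)
  list(difference = diff, band = band, max_abs = max(abs(diff)),
       wavelength_at_max = if (!is.null(ga)) ga[i_max] else i_max,
       verdict = if (all(inside)) "indistinguishable" else "distinguishable")
}

#' Study report table
#'
#' Formats calibration + external validation results for a set of
#' analyte models as a plain-text table (Range, R2, SEC/RMSEC, SEP/
#' RMSEP per analyte).
#'
#' @param models named list of `calibration_model`s.
#' @return character vector of report lines (also printed).
#' @export
format_study_report <- function(models) {
  lines <- c(sprintf("%-12s %-10s %8s %8s %8s %8s %8s",
                     "analyte", "range", "R2.cal", "RMSEC", "R2.val",
                     "RMSEP", "SEP"))
  for (nm in names(models)) {
    m <- models[[nm]]
    tr <- m$training_stats; va <- m$validation
    lines <- c(lines, sprintf(
      "%-12s %4.0f-%-5.0f %8.4f %8.3f %8.4f %8.3f %8.3f",
      nm, m$training_range[1], m$training_range[2], tr$R2, tr$RMSE,
      va$R2, va$RMSE, va$SEP))
  }
  lines
}
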