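#' Shared NIR chromophore library
#'
#' Pure-component NIR band library shared by all default organism
#' profiles. Analyte bands sit in the information-carrying windows
#' 1625-1800 nm (C-H second/first overtones) and 2200-2300 nm (-COOH /
#' -OH combination bands); water dominates everywhere with strong bands
#' at 1450 nm (first O-H overtone) and 1940 nm (O-H combination band)
#' plus an elevated continuum at 1850-2050 nm. Heights are in
#' AU L/(g mm) for analytes and AU/mm for water.
#'
#' All three default organism profiles deliberately share this library:
#' cell-shape-specific chemistry is absent, so mean spectra of different
#' organisms differ only by noise, which is what makes calibration
#' transfer possible.
#'
#' @return an object of class `chromophore_library`: a named list of
#'   band tables `data.frame(center_nm, width_nm, height)`.
#' @export
nir_chromophores <- function() {
  band <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center_nm = m[, 1], width_nm = m[, 2], height = m[, 3])
  }
  lib <- list(
    glucose = band(1688, 18, 0.012,
                   2261, 20, 0.015),
    lactate = band(1724, 16, 0.011,
                   2238, 18, 0.014),
    acetate = band(1742, 15, 0.010,
                   2292, 16, 0.013),
    biomass_chromophore = band(1672, 45, 0.0060,
                               2248, 50, 0.0070),
    water = band(1450, 45, 1.40,
                 1940, 55, 2.60,
                 1150, 35, 0.12,
                 1950, 120, 0.50)
  )
  structure(lib, class = "chromophore_library",
            id = "nirferm-default-chromophores-v1")
}

#' Organism profile
#'
#' Bundles an organism's kinetics, optical scattering strength, cell
#' shape, attainable concentration ranges and the chromophore library
#' its broth spectra are built from.
#'
#' @param name label.
#' @param shape one of `"cluster"`, `"rod"`, `"sphere"`.
#' @param kinetics a [kinetic_params()] object.
#' @param scatter_coefficient baseline scattering per unit biomass,
#'   AU L/(g mm) at 1000 nm.
#' @param chromophores a [nir_chromophores()] library (shared by default).
#' @param medium_glucose initial glucose of the growth medium, g/L.
#' @param init_biomass inoculum biomass, g/L.
#' @param horizon batch duration used for calibration designs, h.
#' @param table_ranges named list of `c(lo, hi)` attainable ranges, g/L.
#' @return an object of class `organism_profile`.
#' @export
organism_profile <- function(name, shape = c("cluster", "rod", "sphere"),
                             kinetics, scatter_coefficient,
                             chromophores = nir_chromophores(),
                             medium_glucose, init_biomass = 0.1,
                             horizon = 48, table_ranges) {
  shape <- match.arg(shape)
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(chromophores, "chromophore_library"))
  check_number(scatter_coefficient, "scatter_coefficient", lower = 0)
  check_number(medium_glucose, "medium_glucose", lower = 0)
  structure(list(name = name, shape = shape, kinetics = kinetics,
                 scatter_coefficient = scatter_coefficient,
                 chromophores = chromophores,
                 medium_glucose = medium_glucose,
                 init_biomass = init_biomass, horizon = horizon,
                 table_ranges = table_ranges),
            class = "organism_profile")
}

#' Default homolactic organism (anaerobic, MRS-type medium, 100 g/L glucose)
#'
#' A homofermentative lactic acid bacterium: lactate is the sole product.
#' Kinetic defaults are frozen so that a default 48 h batch from 100 g/L
#' glucose spans glucose 0-87, lactate 0-98 and biomass 0-16 g/L.
#'
#' @return an [organism_profile()].
#' @export
organism_homolactic <- function() {
  organism_profile(
    name = "homolactic_LAB", shape = "rod",
    kinetics = kinetic_params(mu_max = 0.45, Ks = 0.5, P_max = 98,
                              Y_xs = 0.16, alpha = 5.8, beta = 0.04,
                              acetate_fraction = 0, m = 0.045),
    scatter_coefficient = 0.017,
    medium_glucose = 100, init_biomass = 0.1, horizon = 48,
    table_ranges = list(glucose = c(0, 87), lactate = c(0, 98),
                        acetate = c(0, 0), biomass = c(0, 16)))
}

#' Default heterolactic organisms (aerobic, M53-type medium, 46 g/L glucose)
#'
#' Three heterofermentative profiles differing in cell shape (cluster,
#' rod, sphere), mild kinetic differences and scattering strength, but
#' sharing one chromophore library: their NIR spectra carry no
#' shape-specific features, so calibrations transfer between them.
#'
#' @param shape `"cluster"` (the calibration workhorse), `"rod"` or
#'   `"sphere"`.
#' @return an [organism_profile()].
#' @export
organism_heterolactic <- function(shape = c("cluster", "rod", "sphere")) {
  shape <- match.arg(shape)
  kin <- switch(shape,
    cluster = kinetic_params(mu_max = 0.55, Ks = 0.4, P_max = 40,
                             Y_xs = 0.34, alpha = 2.70, beta = 0.03,
                             acetate_fraction = 0.45, m = 0.035),
    rod = kinetic_params(mu_max = 0.50, Ks = 0.45, P_max = 38,
                         Y_xs = 0.34, alpha = 2.55, beta = 0.03,
                         acetate_fraction = 0.40, m = 0.035),
    sphere = kinetic_params(mu_max = 0.48, Ks = 0.5, P_max = 42,
                            Y_xs = 0.27, alpha = 2.57, beta = 0.03,
                            acetate_fraction = 0.25, m = 0.035))
  ranges <- switch(shape,
    cluster = list(glucose = c(0, 58), lactate = c(0, 23),
                   acetate = c(0, 19), biomass = c(0, 16)),
    rod = list(glucose = c(0, 56), lactate = c(0, 22),
               acetate = c(0, 15), biomass = c(0, 16)),
    sphere = list(glucose = c(0, 50), lactate = c(0, 24),
                  acetate = c(0, 8), biomass = c(0, 12)))
  organism_profile(
    name = paste0("heterolactic_", shape), shape = shape,
    kinetics = kin,
    scatter_coefficient = switch(shape, cluster = 0.018, rod = 0.017,
                                 sphere = 0.016),
    medium_glucose = 46, init_biomass = 0.1, horizon = 36,
    table_ranges = ranges)
}

jitter_kinetics <- function(kin, frac = 0.2) {
  j <- function(x) x * stats::runif(1, 1 - frac, 1 + frac)
  kinetic_params(mu_max = j(kin$mu_max), Ks = j(kin$Ks),
                 P_max = j(kin$P_max), Y_xs = min(1, j(kin$Y_xs)),
                 alpha = j(kin$alpha), beta = j(kin$beta),
                 acetate_fraction = kin$acetate_fraction, m = j(kin$m))
}

#' Design a calibration set of broth states
#'
#' Samples `n` broth states from time points of several simulated batch
#' fermentations whose kinetic parameters are jittered by +/-20% (and
#' whose initial glucose varies by -20%/+25%, emulating medium batch
#' variation). Sampling whole trajectories rather than independent
#' uniform draws preserves the strong substrate-product correlation of
#' real fermentation broths, which a calibration must be built on.
#'
#' @param n number of states (>= 10).
#' @param organism an [organism_profile()].
#' @param seed integer seed.
#' @param n_trajectories number of jittered batches to sample from
#'   (default between 9 and 16 depending on `n`).
#' @param dt integration step, h.
#' @return a `broth_design` data frame (one row per state) with the
#'   trajectory id in column `run`; warns if any analyte covers less
#'   than 90% of the organism's attainable range.
#' @export
design_calibration_states <- function(n, organism, seed = 1L,
                                      n_trajectories = NULL, dt = 0.05) {
  stopifnot(inherits(organism, "organism_profile"))
  if (!is.numeric(n) || n < 10) stop_config("n must be >= 10")
  n <- as.integer(n)
  n_traj <- n_trajectories %||% min(16L, max(9L, as.integer(ceiling(n / 6))))
  states <- with_seed(seed, {
    per <- diff(round(seq(0, n, length.out = n_traj + 1L)))
    rows <- vector("list", n_traj)
    for (k in seq_len(n_traj)) {
      kin <- jitter_kinetics(organism$kinetics)
      s0 <- organism$medium_glucose * stats::runif(1, 0.80, 1.25)
      x0 <- organism$init_biomass * stats::runif(1, 0.8, 1.2)
      tr <- simulate_batch(kin, broth_state(s0, biomass = x0),
                           horizon = organism$horizon, dt = dt)
      idx <- unique(round(seq(1L, nrow(tr), length.out = max(per[k], 1L))))
      sel <- tr[idx, , drop = FALSE]
      sel$run <- k
      rows[[k]] <- sel
    }
    do.call(rbind, rows)
  })
  states <- states[seq_len(min(n, nrow(states))), , drop = FALSE]
  rownames(states) <- NULL
  # coverage report against the organism's attainable ranges
  cov <- vapply(c("glucose", "lactate", "acetate", "biomass"), function(a) {
    rng <- organism$table_ranges[[a]]
    if (diff(rng) <= 0) return(NA_real_)
    span <- diff(range(states[[paste0(a, "_gL")]]))
    span / diff(rng)
  }, numeric(1))
  low <- names(cov)[!is.na(cov) & cov < 0.9]
  if (length(low))
    warning("calibration design covers < 90% of the attainable range for: ",
            paste(low, collapse = ", "), call. = FALSE)
  structure(states, class = c("broth_design", "data.frame"),
            coverage = cov, seed = seed, organism = organism$name)
}
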