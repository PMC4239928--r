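#' Instrument specification
#'
#' The two geometries of the study plus a full-range variant:
#' * `filter19` - a 19-filter reflectance analyzer (1445-2348 nm) on an
#'   external flow-cell loop; effective optical path 0.4 mm (double pass
#'   through the 0.2 mm cell).
#' * `fullspectrum` - a scanning spectrometer, 700-2500 nm, 2 nm steps.
#' * `probe` - the transflectance immersion probe: same spectrometer but
#'   fiber attenuation caps the grid at 1800 nm; 1 mm slit giving a 2 mm
#'   optical path.
#'
#' Absorbance linearity is lost above `absorbance_cap` (4 AU); channels
#' driven past the cap are compressed by [saturate()] and flagged.
#'
#' @param geometry `"filter19"`, `"fullspectrum"` or `"probe"`.
#' @param wavelengths grid, nm, strictly increasing.
#' @param optical_path mm.
#' @param absorbance_cap AU, default 4.
#' @param photometric_noise_sd AU.
#' @param mode `"reflectance"` or `"transflectance"`.
#' @return an object of class `instrument_spec`.
#' @export
instrument_spec <- function(geometry = c("filter19", "fullspectrum", "probe"),
                            wavelengths, optical_path,
                            absorbance_cap = 4,
                            photometric_noise_sd = 5e-4,
                            mode = c("reflectance", "transflectance")) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop_config("wavelengths must be strictly increasing")
  if (geometry == "filter19") {
    if (length(wavelengths) != 19L ||
        any(wavelengths < 1445) || any(wavelengths > 2348))
      stop_config("filter19 grid must be 19 wavelengths within [1445, 2348]")
  } else if (geometry == "probe") {
    if (min(wavelengths) < 700 || max(wavelengths) > 1800)
      stop_config("probe grid must lie within [700, 1800]")
    if (optical_path != 2)
      stop_config("probe optical path is 2 mm (1 mm slit, transflectance)")
  } else {
    if (min(wavelengths) < 700 || max(wavelengths) > 2500)
      stop_config("fullspectrum grid must lie within [700, 2500]")
  }
  check_number(optical_path, "optical_path", lower = 0)
  check_number(absorbance_cap, "absorbance_cap", lower = 0)
  check_number(photometric_noise_sd, "photometric_noise_sd", lower = 0)
  structure(list(geometry = geometry, wavelengths = as.numeric(wavelengths),
                 optical_path = optical_path,
                 absorbance_cap = absorbance_cap,
                 photometric_noise_sd = photometric_noise_sd, mode = mode),
            class = "instrument_spec")
}

#' @rdname instrument_spec
#' @param wavelengths_override optional custom 19-filter wavelength set.
#' @export
instrument_filter19 <- function(wavelengths_override = NULL) {
  wl <- wavelengths_override %||% seq(1445, 2348, length.out = 19)
  instrument_spec("filter19", wl, optical_path = 0.4,
                  photometric_noise_sd = 3e-4, mode = "reflectance")
}

#' @rdname instrument_spec
#' @export
instrument_fullspectrum <- function() {
  instrument_spec("fullspectrum", seq(700, 2500, by = 2), optical_path = 2,
                  photometric_noise_sd = 5e-4, mode = "transflectance")
}

#' @rdname instrument_spec
#' @export
instrument_probe <- function() {
  instrument_spec("probe", seq(700, 1800, by = 2), optical_path = 2,
                  photometric_noise_sd = 5e-4, mode = "transflectance")
}

#' Hydrodynamic state of the reactor
#'
#' @param stirring rpm, in `[0, 1000]`.
#' @param airflow L/min, in `[0, 1.5]`.
#' @return an object of class `hydrodynamic_state`.
#' @export
hydrodynamic_state <- function(stirring = 0, airflow = 0) {
  check_number(stirring, "stirring", lower = 0, upper = 1000)
  check_number(airflow, "airflow", lower = 0, upper = 1.5)
  structure(list(stirring = stirring, airflow = airflow),
            class = "hydrodynamic_state")
}

eval_bands <- function(bands, grid) {
  out <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$height[i] *
      exp(-0.5 * ((grid - bands$center_nm[i]) / bands$width_nm[i])^2)
  }
  out
}

#' Pure-component extinction curve
#'
#' Sum-of-Gaussians extinction curve for one component of the
#' chromophore library, evaluated on a wavelength grid.
#'
#' @param component `"glucose"`, `"lactate"`, `"acetate"`,
#'   `"biomass_chromophore"` or `"water"`.
#' @param grid wavelengths, nm, sorted ascending.
#' @param library a [nir_chromophores()] library.
#' @return numeric vector, AU L/(g mm) (AU/mm for water).
#' @export
pure_component_spectrum <- function(component, grid,
                                    library = nir_chromophores()) {
  if (is.unsorted(grid)) stop_config("grid must be sorted ascending")
  if (!component %in% names(library))
    stop_config("unknown component: ", component)
  eval_bands(library[[component]], grid)
}

# fixed water background of the broth (per mm of optical path), plus a
# small flat continuum
water_absorbance <- function(grid, path, library = nir_chromophores()) {
  path * (eval_bands(library$water, grid) + 0.02)
}

# wavelength^-1 scattering-like baseline from suspended cells
scatter_term <- function(X, grid, coef, path) {
  path * coef * X * (1000 / grid)
}

#' Bubble-induced baseline shift
#'
#' Additive baseline from the air-bubble population in the probe gap.
#' Stirring dominates over airflow (stronger effect on bubble size and
#' fluid velocity) and the effect is attenuated at high biomass, where
#' cell scattering hides the bubbles:
#' \deqn{b(\lambda) = k_{rpm}\, (rpm/1000)\, (1 + k_q\, q)\,
#'       e^{-X/X_{att}}\, (1000/\lambda)}
#' with \eqn{X_{att} = 7} g/L.
#'
#' @param hydro a [hydrodynamic_state()].
#' @param X biomass concentration, g/L.
#' @param grid wavelengths, nm.
#' @return additive baseline, AU.
#' @export
bubble_baseline <- function(hydro, X, grid) {
  stopifnot(inherits(hydro, "hydrodynamic_state"))
  check_number(X, "X", lower = 0)
  k_rpm <- 0.35
  k_q <- 0.4
  X_att <- 7
  k_rpm * (hydro$stirring / 1000) * (1 + k_q * hydro$airflow) *
    exp(-X / X_att) * (1000 / grid)
}

#' Compress absorbance beyond the linearity limit
#'
#' Identity up to the 4 AU cap; above it a smooth, bounded, monotone
#' compression `cap + kappa * (1 - exp(-(A - cap)/kappa))` with
#' continuous value and first derivative at the cap.
#'
#' @param A absorbance, AU (finite).
#' @param cap linearity limit, AU (default 4).
#' @param kappa compression scale, AU (default 0.5); saturated output
#'   stays within `(cap, cap + kappa]`.
#' @return compressed absorbance, AU.
#' @export
saturate <- function(A, cap = 4, kappa = 0.5) {
  if (any(!is.finite(A))) stop_config("A must be finite")
  ifelse(A <= cap, A, cap + kappa * (1 - exp(-(A - cap) / kappa)))
}

#' Generate a synthetic NIR spectrum of a broth state
#'
#' Effective-path Beer-Lambert mixture model:
#' \deqn{A(\lambda) = sat\big(d \sum_c \epsilon_c(\lambda) C_c +
#'   A_{water}(\lambda) + scatter(X, \lambda) +
#'   b_{bubble}(\lambda)\big) + noise}
#' Components are additive below the 4 AU linearity cap; channels whose
#' pre-saturation absorbance exceeds the cap are flagged in the
#' `saturated` field.
#'
#' @param state a [broth_state()].
#' @param instrument an [instrument_spec()].
#' @param hydro a [hydrodynamic_state()] (default: still broth).
#' @param organism an [organism_profile()] supplying the chromophore
#'   library and scattering coefficient.
#' @param seed integer seed of the photometric noise (NULL = zero noise
#'   unless the instrument's `photometric_noise_sd` is zero anyway; with
#'   a NULL seed noise is drawn from the ambient RNG).
#' @return an object of class `nir_spectrum`: list with `wavelengths`,
#'   `absorbance`, `saturated`, `instrument`, `time`.
#' @export
generate_spectrum <- function(state, instrument,
                              hydro = hydrodynamic_state(),
                              organism = organism_heterolactic("cluster"),
                              seed = NULL) {
  stopifnot(inherits(state, "broth_state"),
            inherits(instrument, "instrument_spec"),
            inherits(organism, "organism_profile"))
  grid <- instrument$wavelengths
  A <- spectrum_clean(state, instrument, hydro, organism)
  sat <- A > instrument$absorbance_cap
  A_out <- saturate(A, instrument$absorbance_cap)
  if (instrument$photometric_noise_sd > 0) {
    noise <- with_seed(seed,
                       stats::rnorm(length(grid),
                                    sd = instrument$photometric_noise_sd))
    A_out <- A_out + noise
  }
  structure(list(wavelengths = grid, absorbance = A_out, saturated = sat,
                 instrument = instrument$geometry, time = state$time),
            class = "nir_spectrum")
}

# noise-free pre-saturation absorbance
spectrum_clean <- function(state, instrument, hydro, organism) {
  grid <- instrument$wavelengths
  d <- instrument$optical_path
  lib <- organism$chromophores
  conc <- c(glucose = state$glucose, lactate = state$lactate,
            acetate = state$acetate, biomass_chromophore = state$biomass)
  A <- water_absorbance(grid, d, lib)
  for (comp in names(conc)) {
    if (conc[[comp]] > 0)
      A <- A + d * conc[[comp]] * pure_component_spectrum(comp, grid, lib)
  }
  A <- A + scatter_term(state$biomass, grid, organism$scatter_coefficient, d)
  # bubble artifacts are an immersion-probe phenomenon; the external
  # flow-cell loop (reflectance geometry) sees pumped, bubble-free broth
  if (instrument$mode == "transflectance")
    A <- A + bubble_baseline(hydro, state$biomass, grid)
  A
}

#' Generate a spectra matrix for a design of broth states
#'
#' @param states a `broth_design` (or any data frame with the trajectory
#'   columns).
#' @param instrument an [instrument_spec()].
#' @param hydro a [hydrodynamic_state()] held constant over the set
#'   (stirring is kept constant during calibration runs).
#' @param organism an [organism_profile()].
#' @param seed integer seed for the photometric noise stream.
#' @return numeric matrix (samples x wavelengths) with attributes
#'   `wavelengths` and `saturated` (logical matrix of flagged channels).
#' @export
generate_spectra_matrix <- function(states, instrument,
                                    hydro = hydrodynamic_state(),
                                    organism = organism_heterolactic("cluster"),
                                    seed = NULL) {
  grid <- instrument$wavelengths
  n <- nrow(states)
  X <- matrix(NA_real_, n, length(grid))
  S <- matrix(FALSE, n, length(grid))
  with_seed(seed, {
    for (i in seq_len(n)) {
      st <- broth_state(states$glucose_gL[i], states$lactate_gL[i],
                        states$acetate_gL[i], states$biomass_gL[i],
                        volume = states$volume_L[i],
                        time = states$time_h[i])
      sp <- generate_spectrum(st, instrument, hydro, organism, seed = NULL)
      X[i, ] <- sp$absorbance
      S[i, ] <- sp$saturated
    }
  })
  dimnames(X) <- list(NULL, format(grid, trim = TRUE))
  structure(X, wavelengths = grid, saturated = S)
}
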