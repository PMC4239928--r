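#' Kinetic parameters for a lactic fermentation
#'
#' Monod growth with product (lactate) inhibition and Luedeking-Piret
#' product formation:
#' \deqn{\mu = \mu_{max} \frac{S}{K_s + S} \max(0, 1 - P_L/P_{max})}
#' \deqn{dX/dt = \mu X, \quad dP/dt = (\alpha \mu + \beta f_S) X, \quad
#'       dS/dt = -(\mu/Y_{xs}) X - m f_S X}
#' where \eqn{f_S = S/(K_s+S)}. Product formation is split between lactate
#' and acetate by `acetate_fraction` (0 for a homolactic organism). The
#' non-growth production rate `beta` and the maintenance demand `m` are
#' gated by the substrate Monod factor \eqn{f_S} so that neither product
#' formation nor glucose consumption continues once the substrate is
#' exhausted (see the methods vignette).
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param Ks substrate half-saturation constant, g/L.
#' @param P_max lactate concentration at which growth ceases, g/L.
#' @param Y_xs biomass yield on glucose, g/g (must be <= 1).
#' @param alpha growth-associated product yield, g product / g biomass.
#' @param beta non-growth-associated specific production, g/(g h).
#' @param acetate_fraction fraction of product flux going to acetate, in
#'   `[0, 1]`; 0 means homolactic.
#' @param m maintenance glucose demand, g glucose/(g biomass h).
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(mu_max, Ks, P_max, Y_xs, alpha, beta,
                           acetate_fraction = 0, m = 0) {
  check_number(mu_max, "mu_max", lower = 0)
  check_number(Ks, "Ks", lower = 0)
  check_number(P_max, "P_max", lower = 0)
  check_number(Y_xs, "Y_xs", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0)
  check_number(acetate_fraction, "acetate_fraction", lower = 0, upper = 1)
  check_number(m, "m", lower = 0)
  structure(list(mu_max = mu_max, Ks = Ks, P_max = P_max, Y_xs = Y_xs,
                 alpha = alpha, beta = beta,
                 acetate_fraction = acetate_fraction, m = m),
            class = "kinetic_params")
}

#' Broth state at one time point
#'
#' Concentrations of the four monitored culture components plus the
#' culture volume and time stamp.
#'
#' @param glucose,lactate,acetate,biomass concentrations, g/L (>= 0).
#' @param volume culture volume, L (> 0).
#' @param time time, h.
#' @return an object of class `broth_state`.
#' @export
broth_state <- function(glucose, lactate = 0, acetate = 0, biomass = 0,
                        volume = 2, time = 0) {
  check_number(glucose, "glucose", lower = 0)
  check_number(lactate, "lactate", lower = 0)
  check_number(acetate, "acetate", lower = 0)
  check_number(biomass, "biomass", lower = 0)
  check_number(volume, "volume")
  if (volume <= 0) stop_config("volume must be > 0")
  check_number(time, "time")
  structure(list(glucose = glucose, lactate = lactate, acetate = acetate,
                 biomass = biomass, volume = volume, time = time),
            class = "broth_state")
}

#' Reactor configuration
#'
#' @param mode one of `"batch"`, `"fed"`, `"continuous"`.
#' @param feed_concentration glucose concentration of the feed, g/L.
#' @param working_volume nominal working volume, L (2 L bench reactor).
#' @param stirring agitation rate, rpm, in `[0, 1000]`.
#' @param airflow aeration, L/min, in `[0, 1.5]`.
#' @return an object of class `reactor_config`.
#' @export
reactor_config <- function(mode = c("batch", "fed", "continuous"),
                           feed_concentration = 0, working_volume = 2,
                           stirring = 0, airflow = 0) {
  mode <- match.arg(mode)
  check_number(feed_concentration, "feed_concentration", lower = 0)
  check_number(working_volume, "working_volume", lower = 0.1)
  check_number(stirring, "stirring", lower = 0, upper = 1000)
  check_number(airflow, "airflow", lower = 0, upper = 1.5)
  structure(list(mode = mode, feed_concentration = feed_concentration,
                 working_volume = working_volume, stirring = stirring,
                 airflow = airflow),
            class = "reactor_config")
}

# Right-hand side of the mass balances. `state` is the numeric vector
# c(S, PL, PA, X, V). Inflow is sterile, product-free glucose feed;
# `outflow_broth` carries broth at culture composition (no concentration
# change); `outflow_permeate` is cell-retaining microfiltration (cells
# concentrate, solute concentrations unchanged).
ferm_derivs <- function(state, kin, inflow = 0, outflow_broth = 0,
                        outflow_permeate = 0, feed_conc = 0) {
  S <- max(state[1L], 0); PL <- max(state[2L], 0)
  PA <- max(state[3L], 0); X <- max(state[4L], 0); V <- state[5L]
  fS <- S / (kin$Ks + S)
  mu <- kin$mu_max * fS * max(0, 1 - PL / kin$P_max)
  qP <- (kin$alpha * mu + kin$beta * fS) * X
  dS <- -(mu / kin$Y_xs) * X - kin$m * fS * X
  dPL <- (1 - kin$acetate_fraction) * qP
  dPA <- kin$acetate_fraction * qP
  dX <- mu * X
  dV <- inflow - outflow_broth - outflow_permeate
  if (inflow > 0 && V > 0) {
    dS <- dS + (inflow / V) * (feed_conc - S)
    dPL <- dPL - (inflow / V) * PL
    dPA <- dPA - (inflow / V) * PA
    dX <- dX - (inflow / V) * X
  }
  if (outflow_permeate > 0 && V > 0) {
    dX <- dX + (outflow_permeate / V) * X  # cells retained while V shrinks
  }
  c(dS, dPL, dPA, dX, dV)
}

# One classical fixed-step RK4 step followed by clamping of concentrations
# at zero (the gated kinetics make true undershoot O(dt^4)).
rk4_step <- function(state, dt, kin, inflow = 0, outflow_broth = 0,
                     outflow_permeate = 0, feed_conc = 0) {
  f <- function(s) ferm_derivs(s, kin, inflow, outflow_broth,
                               outflow_permeate, feed_conc)
  k1 <- f(state)
  k2 <- f(state + dt / 2 * k1)
  k3 <- f(state + dt / 2 * k2)
  k4 <- f(state + dt * k3)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out[1:4] <- pmax(out[1:4], 0)
  if (any(!is.finite(out)))
    stop("non-finite state reached during integration (parameter blow-up)")
  out
}

traj_row <- function(t, s, event = "") {
  data.frame(time_h = t, glucose_gL = s[1L], lactate_gL = s[2L],
             acetate_gL = s[3L], biomass_gL = s[4L], volume_L = s[5L],
             event = event, stringsAsFactors = FALSE)
}

state_vec <- function(init) {
  c(init$glucose, init$lactate, init$acetate, init$biomass, init$volume)
}

#' Simulate an open-loop fermentation
#'
#' Integrates the fermentation mass balances with externally prescribed
#' feed and withdrawal profiles. With both profiles identically zero this
#' reduces exactly (bitwise) to [simulate_batch()].
#'
#' @param kinetics a [kinetic_params()] object.
#' @param init initial [broth_state()].
#' @param reactor a [reactor_config()]; bounds the admissible volume.
#' @param feed_profile,withdrawal_profile functions of time (h) returning
#'   nonnegative flows in L/h.
#' @param horizon simulation horizon, h.
#' @param dt integration step, h (default 0.05).
#' @param seed integer seed recorded for provenance (the integration
#'   itself is deterministic).
#' @return a `fermentation_trajectory` data frame with columns `time_h`,
#'   `glucose_gL`, `lactate_gL`, `acetate_gL`, `biomass_gL`, `volume_L`,
#'   `event`.
#' @export
simulate_open_loop <- function(kinetics, init, reactor = reactor_config(),
                               feed_profile = function(t) 0,
                               withdrawal_profile = function(t) 0,
                               horizon, dt = 0.05, seed = NULL) {
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(init, "broth_state"))
  check_number(horizon, "horizon", lower = .Machine$double.eps)
  check_number(dt, "dt", lower = .Machine$double.eps)
  n_steps <- ceiling(horizon / dt - 1e-9)
  s <- state_vec(init)
  times <- init$time + seq(0, by = dt, length.out = n_steps + 1L)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 5L)
  out[1L, ] <- s
  for (i in seq_len(n_steps)) {
    t <- times[i]
    fin <- feed_profile(t); fout <- withdrawal_profile(t)
    if (fin < 0 || fout < 0)
      stop_config("feed/withdrawal profiles must be nonnegative (t = ", t, ")")
    s <- rk4_step(s, dt, kinetics, inflow = fin, outflow_broth = fout,
                  feed_conc = reactor$feed_concentration)
    if (s[5L] < 0.1 - 1e-9 || s[5L] > reactor$working_volume + 1e-9)
      stop("volume left [0.1, working_volume] at t = ",
           format(times[i + 1L], digits = 6), " h (V = ",
           format(s[5L], digits = 6), " L)")
    out[i + 1L, ] <- s
  }
  traj <- data.frame(time_h = times, glucose_gL = out[, 1L],
                     lactate_gL = out[, 2L], acetate_gL = out[, 3L],
                     biomass_gL = out[, 4L], volume_L = out[, 5L],
                     event = "", stringsAsFactors = FALSE)
  structure(traj, class = c("fermentation_trajectory", "data.frame"),
            kinetics = kinetics, dt = dt, seed = seed)
}

#' Simulate a batch fermentation
#'
#' @inheritParams simulate_open_loop
#' @return a `fermentation_trajectory`; see [simulate_open_loop()].
#' @export
simulate_batch <- function(kinetics, init, horizon, dt = 0.05, seed = NULL) {
  simulate_open_loop(kinetics, init,
                     reactor = reactor_config(working_volume =
                                                max(2, init$volume)),
                     horizon = horizon, dt = dt, seed = seed)
}

#' Integration error by step halving
#'
#' Re-integrates a batch run at `dt/2` and returns the largest absolute
#' state discrepancy (g/L) at the coarse time points. Used to validate
#' the default fixed step.
#'
#' @inheritParams simulate_batch
#' @return max absolute concentration difference, g/L.
#' @export
step_halving_error <- function(kinetics, init, horizon, dt = 0.05) {
  a <- simulate_batch(kinetics, init, horizon, dt)
  b <- simulate_batch(kinetics, init, horizon, dt / 2)
  cols <- c("glucose_gL", "lactate_gL", "acetate_gL", "biomass_gL")
  bb <- b[match(round(a$time_h, 9), round(b$time_h, 9)), cols]
  max(abs(as.matrix(a[, cols]) - as.matrix(bb)))
}

#' Reference-assay noise model
#'
#' Additive zero-mean Gaussian assay noise per analyte, truncated at zero.
#' The default dry-weight biomass assay is noisier *relative to its range*
#' (0-16 g/L) than the HPLC analytes are to theirs.
#'
#' @param sd_glucose,sd_lactate,sd_acetate,sd_biomass assay standard
#'   deviations, g/L.
#' @param seed integer seed of the assay noise stream.
#' @return an object of class `assay_noise_model` carrying its own
#'   advancing RNG stream.
#' @export
assay_noise_model <- function(sd_glucose = 1.0, sd_lactate = 1.0,
                              sd_acetate = 1.0, sd_biomass = 0.8,
                              seed = 1L) {
  for (nm in c("sd_glucose", "sd_lactate", "sd_acetate", "sd_biomass")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_config(nm, " must be a nonnegative number")
  }
  e <- new.env(parent = emptyenv())
  e$rng_state <- NULL
  structure(list(sd_glucose = sd_glucose, sd_lactate = sd_lactate,
                 sd_acetate = sd_acetate, sd_biomass = sd_biomass,
                 seed = as.integer(seed), stream = e),
            class = "assay_noise_model")
}

# draw n iid N(0,1) from the noise model's private advancing stream
assay_draw <- function(noise, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(noise$stream$rng_state)) set.seed(noise$seed)
  else assign(".Random.seed", noise$stream$rng_state, envir = globalenv())
  z <- stats::rnorm(n)
  noise$stream$rng_state <- get(".Random.seed", globalenv())
  z
}

#' Noisy off-line reference assay of a broth state
#'
#' Emulates the HPLC (glucose, lactate, acetate) and dry-weight (biomass)
#' reference measurements: unbiased additive Gaussian noise per analyte.
#' Measured values near zero may come out slightly negative, exactly as
#' blank-subtracted gravimetric and chromatographic readings do; clipping
#' them at zero would bias the low-concentration end of every calibration
#' upward (see the methods vignette). Repeated calls on the same model
#' advance its seeded stream.
#'
#' @param state a [broth_state()].
#' @param noise an [assay_noise_model()].
#' @return named numeric vector `c(glucose, lactate, acetate, biomass)`,
#'   g/L.
#' @export
reference_assay <- function(state, noise) {
  stopifnot(inherits(state, "broth_state"),
            inherits(noise, "assay_noise_model"))
  z <- assay_draw(noise, 4L)
  truth <- c(state$glucose, state$lactate, state$acetate, state$biomass)
  sds <- c(noise$sd_glucose, noise$sd_lactate, noise$sd_acetate,
           noise$sd_biomass)
  out <- truth + z * sds   # unbiased: no clipping at zero
  names(out) <- c("glucose", "lactate", "acetate", "biomass")
  out
}

# assay a whole design table at once; returns an n x 4 matrix
assay_states <- function(states, noise) {
  out <- matrix(NA_real_, nrow(states), 4L,
                dimnames = list(NULL, c("glucose", "lactate", "acetate",
                                        "biomass")))
  for (i in seq_len(nrow(states))) {
    st <- broth_state(states$glucose_gL[i], states$lactate_gL[i],
                      states$acetate_gL[i], states$biomass_gL[i],
                      volume = states$volume_L[i], time = states$time_h[i])
    out[i, ] <- reference_assay(st, noise)
  }
  out
}
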