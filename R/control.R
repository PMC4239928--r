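# Closed-loop NIR-feedback operating strategies. The controller observes
# only NIR-predicted concentrations (plus the physical volume, which the
# reactor's weight-control system measures directly); true concentrations
# are never read by any decision rule.

#' Control strategies
#'
#' Constructors for the five NIR-feedback operating policies:
#' * `strategy_rbc()` - repeated batch: when predicted lactate reaches
#'   `lactate_trigger`, harvest down to `V_low`, then refill with fresh
#'   medium to `V_work`.
#' * `strategy_rfbc()` - repeated fed-batch: feed at `feed_rate` from
#'   `V0` to `Vf`, then discharge back to `V0`; NIR only monitors.
#' * `strategy_turbidostat()` - constant-volume continuous culture
#'   holding predicted biomass at a setpoint (piecewise-constant
#'   schedule allowed) by modulating the dilution rate.
#' * `strategy_chemostat()` - as above with predicted glucose as the
#'   controlled variable.
#' * `strategy_rbc_microfiltration()` - fully automated repeated batch:
#'   predicted lactate above `B` starts cell-retaining microfiltration
#'   (biomass concentrates); predicted biomass above `A` triggers
#'   discharge to volume `D`; refill restores the working level `C`.
#'
#' Continuous strategies use a proportional-integral adjustment of the
#' dilution rate on the predicted-vs-setpoint error (gains `Kp`, `Ki`,
#' frozen defaults). Sign convention: predicted biomass above its
#' setpoint, or predicted glucose below its setpoint, increases dilution.
#'
#' @param lactate_trigger,V_low,V_work repeated-batch parameters (g/L, L, L).
#' @return an object of class `control_strategy`.
#' @export
strategy_rbc <- function(lactate_trigger, V_low, V_work = 2) {
  check_number(lactate_trigger, "lactate_trigger", lower = 1e-9)
  if (!(V_low < V_work)) stop_config("need V_low < V_work")
  structure(list(kind = "rbc", lactate_trigger = lactate_trigger,
                 V_low = V_low, V_work = V_work,
                 reads = "lactate"),
            class = "control_strategy")
}

#' @rdname strategy_rbc
#' @param V0,Vf,feed_rate repeated fed-batch parameters (L, L, L/h).
#' @export
strategy_rfbc <- function(V0, Vf, feed_rate) {
  if (!(V0 < Vf)) stop_config("need V0 < Vf")
  check_number(feed_rate, "feed_rate", lower = 1e-9)
  structure(list(kind = "rfbc", V0 = V0, Vf = Vf, feed_rate = feed_rate,
                 reads = character(0)),
            class = "control_strategy")
}

#' @rdname strategy_rbc
#' @param X_set biomass setpoint(s), g/L; either a single value or a
#'   data frame `data.frame(from_h, setpoint)` for a stepped schedule.
#' @param Kp,Ki PI gains (1/h per g/L and 1/h^2 per g/L).
#' @param D_max dilution-rate ceiling, 1/h.
#' @param ewma exponential smoothing weight applied to the predicted
#'   signal before the PI error (1 = no smoothing). Spectrum-to-spectrum
#'   prediction noise otherwise dithers the dilution rate, and the
#'   asymmetric plant response (washout is faster than regrowth)
#'   rectifies that dither into a systematic offset below the setpoint.
#' @export
strategy_turbidostat <- function(X_set, Kp = 0.05, Ki = 0.04, D_max = 1,
                                 ewma = 0.3) {
  sched <- if (is.data.frame(X_set)) X_set
           else data.frame(from_h = 0, setpoint = X_set)
  stopifnot(all(sched$setpoint > 0))
  check_number(ewma, "ewma", lower = 1e-6, upper = 1)
  structure(list(kind = "turbidostat", schedule = sched, Kp = Kp, Ki = Ki,
                 D_max = D_max, ewma = ewma, reads = "biomass"),
            class = "control_strategy")
}

#' @rdname strategy_rbc
#' @param S_set glucose setpoint, g/L.
#' @export
strategy_chemostat <- function(S_set, Kp = 0.02, Ki = 0.03, D_max = 1,
                               ewma = 0.3) {
  check_number(S_set, "S_set", lower = 1e-9)
  check_number(ewma, "ewma", lower = 1e-6, upper = 1)
  structure(list(kind = "chemostat", S_set = S_set, Kp = Kp, Ki = Ki,
                 D_max = D_max, ewma = ewma, reads = "glucose"),
            class = "control_strategy")
}

#' @rdname strategy_rbc
#' @param A biomass discharge threshold, g/L.
#' @param B lactate filtration threshold, g/L.
#' @param C working level, L.
#' @param D residual volume after discharge, L (`D < C`).
#' @param permeate_rate microfiltration permeate flow, L/h.
#' @param refill_rate fresh-medium refill flow, L/h (fast ramp).
#' @export
strategy_rbc_microfiltration <- function(A, B, C = 2, D = 1,
                                         permeate_rate = 0.6,
                                         refill_rate = 20) {
  check_number(A, "A", lower = 1e-9)
  check_number(B, "B", lower = 1e-9)
  if (!(D < C)) stop_config("need D < C")
  structure(list(kind = "rbc_microfiltration", A = A, B = B, C = C, D = D,
                 permeate_rate = permeate_rate, refill_rate = refill_rate,
                 reads = c("lactate", "biomass")),
            class = "control_strategy")
}

# instantaneous harvest to V_low then refill to V_work with fresh medium
# (feed glucose concentration S_feed); returns the updated state vector
rbc_harvest_refill <- function(s, V_low, V_work, S_feed) {
  s[5L] <- V_low                    # harvest: concentrations unchanged
  dil <- V_low / V_work
  s[1L] <- s[1L] * dil + S_feed * (1 - dil)
  s[2L] <- s[2L] * dil
  s[3L] <- s[3L] * dil
  s[4L] <- s[4L] * dil
  s[5L] <- V_work
  s
}

#' One repeated-batch control decision
#'
#' Pure decision rule: harvest-and-refill iff the predicted lactate has
#' reached the trigger.
#'
#' @param state the current [broth_state()] (volume is read; the
#'   concentrations are not used by the rule).
#' @param predicted named vector of NIR-predicted concentrations, g/L.
#' @param strategy a [strategy_rbc()].
#' @return list `(action = "none"|"harvest_refill")`.
#' @export
rbc_step <- function(state, predicted, strategy) {
  if (!is.na(predicted[["lactate"]]) &&
      predicted[["lactate"]] >= strategy$lactate_trigger)
    list(action = "harvest_refill")
  else list(action = "none")
}

#' One microfiltration-RBC state-machine transition
#'
#' IDLE -> FILTERING on predicted lactate >= B; FILTERING -> DISCHARGING
#' on predicted biomass >= A; DISCHARGING -> REFILLING once volume D is
#' reached; REFILLING -> IDLE at working level C.
#'
#' @param phase current phase string.
#' @param state current [broth_state()] (volume read only).
#' @param predicted named vector of predicted concentrations.
#' @param strategy a [strategy_rbc_microfiltration()].
#' @return the next phase string.
#' @export
rbc_microfiltration_step <- function(phase, state, predicted, strategy) {
  V <- if (inherits(state, "broth_state")) state$volume else state[5L]
  switch(phase,
    IDLE = if (!is.na(predicted[["lactate"]]) &&
               predicted[["lactate"]] >= strategy$B) "FILTERING" else "IDLE",
    FILTERING = if (!is.na(predicted[["biomass"]]) &&
                    predicted[["biomass"]] >= strategy$A) "DISCHARGING"
                else "FILTERING",
    DISCHARGING = if (V <= strategy$D + 1e-9) "REFILLING" else "DISCHARGING",
    REFILLING = if (V >= strategy$C - 1e-9) "IDLE" else "REFILLING",
    stop("unknown phase ", phase))
}

pi_dilution <- function(ctrl, error, dt, Kp, Ki, D_max) {
  ctrl$I <- ctrl$I + error * dt
  D <- Kp * error + Ki * ctrl$I
  if (D < 0) { ctrl$I <- ctrl$I - error * dt; D <- max(0, D) }
  ctrl$D <- min(max(D, 0), D_max)
  ctrl
}

current_setpoint <- function(schedule, t) {
  schedule$setpoint[max(which(schedule$from_h <= t + 1e-12))]
}

#' Run a closed-loop NIR-feedback fermentation
#'
#' At every control step a spectrum of the true broth is generated,
#' analyte concentrations are predicted with the supplied calibration
#' models, the strategy decides the actuation (flows, harvest,
#' filtration, discharge), and the simulator advances. The decision
#' rules never read the true concentrations; set `spoof_truth = TRUE`
#' to verify this (the state handed to the decision rules then has its
#' concentrations zeroed, which must not change any actuation).
#'
#' @param config a [study_config()] (supplies organism, instrument,
#'   hydrodynamics, feed medium via the organism's `medium_glucose`).
#' @param models named list of `calibration_model`s covering every
#'   analyte the strategy reads.
#' @param strategy a `control_strategy`.
#' @param horizon simulated duration, h.
#' @param control_dt interval between spectra acquisitions / control
#'   decisions, h (default 0.25).
#' @param init optional initial [broth_state()].
#' @param seed integer seed (photometric noise stream).
#' @param spoof_truth test hook, see above.
#' @return list with `trajectory` (true and predicted concentrations,
#'   volume, dilution rate per control step) and `events` (an event-log
#'   data frame).
#' @export
run_closed_loop <- function(config, models, strategy, horizon,
                            control_dt = 0.25, init = NULL, seed = 1L,
                            spoof_truth = FALSE) {
  stopifnot(inherits(config, "study_config"),
            inherits(strategy, "control_strategy"))
  for (a in strategy$reads)
    if (is.null(models[[a]]))
      stop_config("strategy reads '", a, "' but no model was supplied")
  org <- config$organism
  kin <- org$kinetics
  dt <- 0.05
  n_sub <- max(1L, round(control_dt / dt))
  dt <- control_dt / n_sub
  init <- init %||% broth_state(org$medium_glucose,
                                biomass = org$init_biomass, volume = 2)
  s <- state_vec(init)
  V_work <- max(2, init$volume)
  S_feed <- org$medium_glucose
  n_ctrl <- ceiling(horizon / control_dt)
  ctrl <- new.env(parent = emptyenv()); ctrl$I <- 0; ctrl$D <- 0
  phase <- "IDLE"
  rows <- vector("list", n_ctrl + 1L)
  events <- list()
  log_event <- function(t, what, V, analyte = NA, value = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      time_h = t, event = what, volume_L = V,
      trigger_analyte = as.character(analyte),
      predicted_value_gL = as.numeric(value), stringsAsFactors = FALSE)
  }
  analytes <- c("glucose", "lactate", "acetate", "biomass")
  predict_all <- function(sv, t) {
    st <- broth_state(sv[1L], sv[2L], sv[3L], sv[4L], volume = sv[5L],
                      time = t)
    sp <- generate_spectrum(st, config$instrument, config$hydro, org,
                            seed = NULL)
    out <- rep(NA_real_, 4); names(out) <- analytes
    for (a in names(models)) out[[a]] <- as.numeric(predict(models[[a]], sp))
    out
  }
  with_seed(seed, {
    for (i in seq_len(n_ctrl + 1L)) {
      t <- (i - 1L) * control_dt
      pred <- predict_all(s, t)
      obs_state <- broth_state(if (spoof_truth) 0 else s[1L],
                               if (spoof_truth) 0 else s[2L],
                               if (spoof_truth) 0 else s[3L],
                               if (spoof_truth) 0 else s[4L],
                               volume = s[5L], time = t)
      F_in <- 0; F_out <- 0; F_perm <- 0
      if (strategy$kind == "rbc") {
        act <- rbc_step(obs_state, pred, strategy)
        if (act$action == "harvest_refill") {
          log_event(t, "harvest", strategy$V_low, "lactate",
                    pred[["lactate"]])
          s <- rbc_harvest_refill(s, strategy$V_low, strategy$V_work,
                                  S_feed)
          log_event(t, "refill", strategy$V_work, "lactate",
                    pred[["lactate"]])
        }
      } else if (strategy$kind == "rfbc") {
        if (s[5L] >= strategy$Vf - 1e-9) {
          log_event(t, "discharge", strategy$V0, NA, NA)
          s[5L] <- strategy$V0   # partial harvest, concentrations unchanged
        } else F_in <- strategy$feed_rate
      } else if (strategy$kind == "turbidostat") {
        sp_now <- current_setpoint(strategy$schedule, t)
        ctrl$f_x <- if (is.null(ctrl$f_x)) pred[["biomass"]] else
          strategy$ewma * pred[["biomass"]] + (1 - strategy$ewma) * ctrl$f_x
        err <- ctrl$f_x - sp_now            # X high -> dilute more
        ctrl <- pi_dilution(ctrl, err, control_dt, strategy$Kp,
                            strategy$Ki, strategy$D_max)
        F_in <- ctrl$D * s[5L]; F_out <- F_in
      } else if (strategy$kind == "chemostat") {
        ctrl$f_x <- if (is.null(ctrl$f_x)) pred[["glucose"]] else
          strategy$ewma * pred[["glucose"]] + (1 - strategy$ewma) * ctrl$f_x
        err <- strategy$S_set - ctrl$f_x    # S low -> dilute more
        ctrl <- pi_dilution(ctrl, err, control_dt, strategy$Kp,
                            strategy$Ki, strategy$D_max)
        F_in <- ctrl$D * s[5L]; F_out <- F_in
      } else if (strategy$kind == "rbc_microfiltration") {
        new_phase <- rbc_microfiltration_step(phase, obs_state, pred,
                                              strategy)
        if (new_phase != phase) {
          what <- switch(new_phase, FILTERING = "filtration_start",
                         DISCHARGING = "discharge",
                         REFILLING = "refill_start", IDLE = "refill_stop")
          trig <- switch(new_phase, FILTERING = "lactate",
                         DISCHARGING = "biomass", NA)
          log_event(t, what, s[5L],
                    trig, if (!is.na(trig)) pred[[trig]] else NA)
          if (new_phase == "REFILLING" && phase == "DISCHARGING")
            s[5L] <- strategy$D
          phase <- new_phase
        }
        if (phase == "FILTERING") F_perm <- strategy$permeate_rate
        if (phase == "DISCHARGING") s[5L] <- strategy$D  # fast pump-out
        if (phase == "REFILLING") F_in <- strategy$refill_rate
      }
      rows[[i]] <- data.frame(
        time_h = t, glucose_gL = s[1L], lactate_gL = s[2L],
        acetate_gL = s[3L], biomass_gL = s[4L], volume_L = s[5L],
        pred_glucose_gL = pred[["glucose"]],
        pred_lactate_gL = pred[["lactate"]],
        pred_acetate_gL = pred[["acetate"]],
        pred_biomass_gL = pred[["biomass"]],
        dilution_rate_h = if (s[5L] > 0) (F_in - 0) / s[5L] *
          (strategy$kind %in% c("turbidostat", "chemostat")) else 0,
        phase = if (strategy$kind == "rbc_microfiltration") phase else "",
        stringsAsFactors = FALSE)
      if (i > n_ctrl) break
      for (j in seq_len(n_sub)) {
        cap_in <- F_in
        if (F_in > 0 && s[5L] >= V_work) cap_in <- F_out  # level reached
        if (strategy$kind == "rbc_microfiltration" && phase == "REFILLING" &&
            s[5L] >= strategy$C - 1e-9) cap_in <- 0       # working level hit
        s <- rk4_step(s, dt, kin, inflow = cap_in, outflow_broth = F_out,
                      outflow_permeate = F_perm, feed_conc = S_feed)
        s[5L] <- min(max(s[5L], min(0.1, strategy$D %||% 0.1)), V_work)
        lo <- if (strategy$kind == "rbc") strategy$V_low
              else if (strategy$kind == "rbc_microfiltration") strategy$D
              else 0.1
        if (s[5L] < lo - 1e-6 || s[5L] > V_work + 1e-6)
          stop("volume bound violated at t = ", t)
      }
    }
  })
  traj <- do.call(rbind, rows)
  traj <- structure(traj, class = c("fermentation_trajectory",
                                    "data.frame"))
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time_h = numeric(0), event = character(0),
               volume_L = numeric(0), trigger_analyte = character(0),
               predicted_value_gL = numeric(0), stringsAsFactors = FALSE)
  list(trajectory = traj, events = structure(ev, class = c("event_log",
                                                           "data.frame")))
}

#' Detect steady state in a continuous-culture trajectory
#'
#' Steady state is declared at the earliest time `t` such that every
#' monitored concentration stays within a relative tolerance of its
#' window mean over `[t, t + 2 * residence_time]`.
#'
#' @param traj a `fermentation_trajectory`.
#' @param residence_time reactor residence time `1/D`, h.
#' @param tolerance relative band half-width (default 0.05); for
#'   near-zero means an absolute floor of 0.5 g/L applies.
#' @return the earliest steady time (h), or `NA` if never steady.
#' @export
steady_state_detect <- function(traj, residence_time, tolerance = 0.05) {
  w <- 2 * residence_time
  t <- traj$time_h
  if (max(t) - min(t) < w)
    stop_config("trajectory shorter than two residence times")
  cols <- c("glucose_gL", "lactate_gL", "acetate_gL", "biomass_gL")
  cols <- cols[vapply(cols, function(cl) any(traj[[cl]] > 1e-6), logical(1))]
  for (i in seq_along(t)) {
    if (t[i] + w > max(t) + 1e-9) break
    in_w <- t >= t[i] - 1e-9 & t <= t[i] + w + 1e-9
    ok <- TRUE
    for (cl in cols) {
      v <- traj[[cl]][in_w]
      m <- mean(v)
      band <- max(tolerance * abs(m), tolerance * 0.5)
      if (any(abs(v - m) > band)) { ok <- FALSE; break }
    }
    if (ok) return(t[i])
  }
  NA_real_
}
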