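# process_control module: decision rules, state machine, closed loops,
# steady-state detection.

make_homo_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fast_homo_cfg(seed = 51, n_cal = 40)
      cache <<- list(
        cfg = cfg,
        glucose = build_calibration(cfg, "glucose"),
        lactate = build_calibration(cfg, "lactate"),
        biomass = build_calibration(cfg, "biomass"))
    }
    cache
  }
})

test_that("rbc decision rule and dilution arithmetic", {
  st <- broth_state(20, lactate = 30, biomass = 5, volume = 2)
  strat <- strategy_rbc(lactate_trigger = 50, V_low = 1, V_work = 2)
  expect_equal(rbc_step(st, c(lactate = 30), strat)$action, "none")
  expect_equal(rbc_step(st, c(lactate = 55), strat)$action,
               "harvest_refill")
  # refill mass balance: non-fed components dilute by V_low/V_work
  s <- nirferm:::rbc_harvest_refill(c(20, 60, 0, 8, 2), 1, 2, 100)
  expect_equal(s[2], 60 * 0.5)   # lactate
  expect_equal(s[4], 8 * 0.5)    # biomass
  expect_equal(s[1], 20 * 0.5 + 100 * 0.5)  # glucose gets feed
  expect_equal(s[5], 2)
})

test_that("closed-loop RBC fires harvest/refill pairs at the trigger", {
  mm <- make_homo_models()
  strat <- strategy_rbc(lactate_trigger = 50, V_low = 1, V_work = 2)
  run <- run_closed_loop(mm$cfg, list(lactate = mm$lactate), strat,
                         horizon = 30, seed = 52)
  ev <- run$events
  expect_gt(nrow(ev), 2)
  harv <- which(ev$event == "harvest")
  expect_true(all(ev$event[harv + 1] == "refill"))
  expect_true(all(ev$predicted_value_gL[harv] >= 50))
  expect_true(all(run$trajectory$volume_L <= 2 + 1e-9))
})

test_that("microfiltration cycle follows the B -> A -> D -> C narrative", {
  mm <- make_homo_models()
  strat <- strategy_rbc_microfiltration(A = 12, B = 40, C = 2, D = 1.2,
                                        permeate_rate = 0.5)
  run <- run_closed_loop(mm$cfg,
                         list(lactate = mm$lactate, biomass = mm$biomass),
                         strat, horizon = 30, seed = 53)
  ev <- run$events
  first4 <- ev$event[1:4]
  expect_equal(first4, c("filtration_start", "discharge", "refill_start",
                         "refill_stop"))
  expect_equal(ev$trigger_analyte[1], "lactate")
  expect_gte(ev$predicted_value_gL[1], 40)
  expect_equal(ev$trigger_analyte[2], "biomass")
  expect_gte(ev$predicted_value_gL[2], 12)
  expect_true(all(run$trajectory$volume_L >= 1.2 - 1e-6 &
                    run$trajectory$volume_L <= 2 + 1e-6))
  # unreachable threshold: no events ever fire
  quiet <- strategy_rbc_microfiltration(A = 12, B = 500, C = 2, D = 1.2)
  run0 <- run_closed_loop(mm$cfg,
                          list(lactate = mm$lactate, biomass = mm$biomass),
                          quiet, horizon = 10, seed = 53)
  expect_equal(nrow(run0$events), 0)
})

test_that("filtration concentrates retained cells by +X f/V", {
  kin <- kinetic_params(mu_max = 0, Ks = 1, P_max = 100, Y_xs = 0.2,
                        alpha = 0, beta = 0)  # no growth: isolate filtration
  d <- nirferm:::ferm_derivs(c(10, 5, 0, 8, 2), kin,
                             outflow_permeate = 0.5)
  expect_equal(d[4], 8 * 0.5 / 2)   # dX/dt = +X f/V
  expect_equal(d[1], 0)             # permeate carries S at broth conc
  expect_equal(d[5], -0.5)
})

test_that("controller actuation depends only on predictions (spoof hook)", {
  mm <- make_homo_models()
  strat <- strategy_turbidostat(7)
  a <- run_closed_loop(mm$cfg, list(biomass = mm$biomass), strat,
                       horizon = 8, seed = 54)
  b <- run_closed_loop(mm$cfg, list(biomass = mm$biomass), strat,
                       horizon = 8, seed = 54, spoof_truth = TRUE)
  expect_identical(a$trajectory$dilution_rate_h, b$trajectory$dilution_rate_h)
  expect_identical(a$events, b$events)
  # and runs are seed-deterministic
  c_ <- run_closed_loop(mm$cfg, list(biomass = mm$biomass), strat,
                        horizon = 8, seed = 54)
  expect_identical(a$trajectory, c_$trajectory)
  # strategy reading an analyte without a model is refused
  expect_error(run_closed_loop(mm$cfg, list(), strat, horizon = 2),
               "no model")
})

test_that("zero-noise continuous loops converge to their setpoints", {
  # the EWMA prediction filter exists to fight sensor noise; with a
  # perfect sensor the law reduces to pure PI (ewma = 1)
  cfg <- fast_hetero_cfg(seed = 55,
                         noise = assay_noise_model(1e-3, 1e-3, 1e-3, 1e-3))
  cfg$instrument <- fast_probe(noise_sd = 1e-8)
  m <- build_calibration(cfg, "glucose")
  run <- run_closed_loop(cfg, list(glucose = m),
                         strategy_chemostat(20, ewma = 1),
                         horizon = 24, seed = 56)
  tr <- run$trajectory
  late <- tr$glucose_gL[tr$time_h >= 16]
  expect_lt(abs(mean(late) - 20) / 20, 0.01)

  mx <- build_calibration(cfg, "biomass")
  run2 <- run_closed_loop(cfg, list(biomass = mx),
                          strategy_turbidostat(6, ewma = 1),
                          horizon = 30, seed = 56)
  late2 <- run2$trajectory$biomass_gL[run2$trajectory$time_h >= 22]
  expect_lt(abs(mean(late2) - 6) / 6, 0.01)
})

test_that("turbidostat: higher setpoint phase runs at lower dilution", {
  mm <- make_homo_models()
  sched <- data.frame(from_h = c(0, 25), setpoint = c(7, 9))
  run <- run_closed_loop(mm$cfg, list(biomass = mm$biomass),
                         strategy_turbidostat(sched), horizon = 45,
                         seed = 57)
  tr <- run$trajectory
  p1 <- tr$time_h >= 15 & tr$time_h < 25
  p2 <- tr$time_h >= 38
  expect_lt(abs(mean(tr$biomass_gL[p1]) - 7) / 7, 0.08)
  expect_lt(abs(mean(tr$biomass_gL[p2]) - 9) / 9, 0.08)
  expect_lt(mean(tr$dilution_rate_h[p2]), mean(tr$dilution_rate_h[p1]))
})

test_that("high-setpoint chemostat drives biomass down after the transient", {
  mm <- make_homo_models()
  run <- run_closed_loop(mm$cfg, list(glucose = mm$glucose),
                         strategy_chemostat(30), horizon = 36, seed = 58)
  tr <- run$trajectory
  i0 <- which(abs(tr$glucose_gL - 30) < 1.5)[1]
  expect_false(is.na(i0))
  keep <- tr$time_h >= tr$time_h[i0] + 2
  xs <- tr$biomass_gL[keep]; ts <- tr$time_h[keep]
  expect_lt(tail(xs, 1), 0.95 * max(tr$biomass_gL))  # net decline
  expect_lt(unname(coef(lm(xs ~ ts))[2]), 0)         # downward trend
})

test_that("steady-state detection: constant, exponential, oscillating", {
  base <- data.frame(time_h = seq(0, 20, 0.25))
  const <- within(base, {glucose_gL <- 10; lactate_gL <- 0; acetate_gL <- 0
                         biomass_gL <- 5; volume_L <- 2})
  expect_equal(steady_state_detect(const, residence_time = 2), 0)
  # exponential approach x(t) = 10 - 8 exp(-k t): the whole window
  # [t, t+2tau] sits in the +/-5% band once 8 exp(-k t) <= tol * mean;
  # check detection against the analytic crossing time
  k <- 0.5
  expo <- within(base, {glucose_gL <- 10 - 8 * exp(-k * time_h)
                        lactate_gL <- 0; acetate_gL <- 0
                        biomass_gL <- 0; volume_L <- 2})
  det <- steady_state_detect(expo, residence_time = 2, tolerance = 0.05)
  # worst in-window deviation from the window mean is c * exp(-k t) with
  # c = A - (A/(kW)) (1 - exp(-kW)); solve c exp(-k t*) = 0.05 * 10
  W <- 4; A <- 8
  cc <- A - (A / (k * W)) * (1 - exp(-k * W))
  t_analytic <- log(cc / (0.05 * 10)) / k
  expect_lt(abs(det - t_analytic), 1)
  osc <- within(base, {glucose_gL <- 10 + 3 * sin(time_h)
                       lactate_gL <- 0; acetate_gL <- 0
                       biomass_gL <- 0; volume_L <- 2})
  expect_true(is.na(steady_state_detect(osc, residence_time = 2)))
  expect_error(steady_state_detect(const[1:4, ], residence_time = 10),
               "shorter")
})
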