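# spectra_sim module: instruments, pure components, mixture law, bubble
# baseline, saturation.

test_that("instrument invariants are enforced", {
  f19 <- instrument_filter19()
  expect_length(f19$wavelengths, 19)
  expect_true(all(f19$wavelengths >= 1445 & f19$wavelengths <= 2348))
  pr <- instrument_probe()
  expect_true(max(pr$wavelengths) <= 1800 && min(pr$wavelengths) >= 700)
  expect_equal(pr$optical_path, 2)
  fs <- instrument_fullspectrum()
  expect_equal(range(fs$wavelengths), c(700, 2500))
  expect_error(instrument_spec("filter19", c(1500, 1400, 1600), 0.4),
               "strictly increasing")
  expect_error(instrument_spec("probe", seq(700, 1900, 2), 2),
               "within")
})

test_that("pure-component curves live in the stated bands", {
  grid <- instrument_fullspectrum()$wavelengths
  for (comp in c("glucose", "lactate", "acetate")) {
    e <- pure_component_spectrum(comp, grid)
    am <- grid[which.max(e)]
    expect_true((am >= 1625 && am <= 1800) || (am >= 2200 && am <= 2300),
                label = paste(comp, "argmax", am))
  }
  # Gaussian tails: 10 widths away from every band the curve is ~ 0
  lib <- nir_chromophores()
  b <- lib$glucose
  far <- 1300  # > 10 widths from both glucose centers
  expect_true(all(abs(far - b$center_nm) > 10 * b$width_nm))
  expect_lt(pure_component_spectrum("glucose", far), 1e-6)
  expect_error(pure_component_spectrum("caffeine", grid), "unknown component")
})

test_that("analyte matrix is well conditioned and water dominates", {
  grid <- instrument_fullspectrum()$wavelengths
  E <- sapply(c("glucose", "lactate", "acetate", "biomass_chromophore"),
              pure_component_spectrum, grid = grid)
  En <- sweep(E, 2, sqrt(colSums(E^2)), "/")
  expect_lt(kappa(En, exact = TRUE), 100)
  w <- pure_component_spectrum("water", grid)
  expect_gte(max(w), 10 * max(E))
})

test_that("blank broth gives the water spectrum alone", {
  pr <- instrument_probe()
  pr$photometric_noise_sd <- 0
  org <- organism_heterolactic("cluster")
  sp <- generate_spectrum(broth_state(0), pr, hydrodynamic_state(0, 0), org)
  expect_equal(sp$absorbance,
               nirferm:::water_absorbance(pr$wavelengths, pr$optical_path),
               tolerance = 1e-12)
  expect_length(generate_spectrum(broth_state(10), instrument_filter19(),
                                  organism = org)$absorbance, 19)
})

test_that("mixture law is additive below the saturation cap", {
  pr <- instrument_probe()
  pr$photometric_noise_sd <- 0
  org <- organism_heterolactic("cluster")
  hy <- hydrodynamic_state(0, 0)
  s  <- function(st) generate_spectrum(st, pr, hy, org)$absorbance
  blank <- s(broth_state(0))
  c1 <- s(broth_state(20, lactate = 5))
  c2 <- s(broth_state(10, acetate = 3))
  c12 <- s(broth_state(30, lactate = 5, acetate = 3))
  expect_equal(c12 - c1 - c2 + blank, rep(0, 551), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("absorbance increases with analyte concentration in its band", {
  pr <- instrument_probe()
  pr$photometric_noise_sd <- 0
  org <- organism_heterolactic("cluster")
  i_band <- which.min(abs(pr$wavelengths - 1724))  # lactate band
  a <- sapply(c(0, 5, 10, 20), function(cc)
    generate_spectrum(broth_state(10, lactate = cc), pr,
                      organism = org)$absorbance[i_band])
  expect_true(all(diff(a) > 0))
  # scatter offset nondecreasing in biomass
  i_nir <- which.min(abs(pr$wavelengths - 1100))
  b <- sapply(c(0, 2, 8, 16), function(x)
    generate_spectrum(broth_state(10, biomass = x), pr,
                      organism = org)$absorbance[i_nir])
  expect_true(all(diff(b) > 0))
})

test_that("bubble baseline: stirring dominates, biomass attenuates", {
  grid <- instrument_probe()$wavelengths
  expect_equal(bubble_baseline(hydrodynamic_state(0, 0), 1, grid),
               rep(0, length(grid)))
  rpm_sweep <- sapply(seq(100, 1000, by = 100), function(r)
    max(abs(bubble_baseline(hydrodynamic_state(r, 0.5), 1, grid))))
  air_sweep <- sapply(seq(0.1, 1.0, by = 0.1), function(q)
    max(abs(bubble_baseline(hydrodynamic_state(500, q), 1, grid))))
  expect_gt(max(rpm_sweep), max(air_sweep))
  expect_true(all(diff(rpm_sweep) > 0))   # monotone in stirring
  expect_true(all(diff(air_sweep) > 0))   # monotone in airflow
  rpm_high_X <- sapply(seq(100, 1000, by = 100), function(r)
    max(abs(bubble_baseline(hydrodynamic_state(r, 0.5), 20, grid))))
  expect_gt(max(rpm_sweep), max(rpm_high_X))  # hidden at high biomass
})

test_that("saturation is identity below 4 AU and a bounded map above", {
  expect_equal(saturate(3), 3)
  expect_equal(saturate(4), 4)
  # C1 continuity at the cap
  eps <- 1e-7
  expect_equal((saturate(4 + eps) - saturate(4 - eps)) / (2 * eps), 1,
               tolerance = 1e-3)
  s10 <- saturate(10, kappa = 0.5)
  expect_true(s10 > 4 && s10 <= 4.5)
  expect_equal(s10, 4 + 0.5 * (1 - exp(-(10 - 4) / 0.5)))
  expect_error(saturate(Inf), "finite")
})

test_that("no fouling drift: repeated spectra of a fixed state are trendless", {
  pr <- instrument_probe()
  org <- organism_heterolactic("cluster")
  st <- broth_state(5, lactate = 20, acetate = 10, biomass = 20)
  times <- seq(0, 20, by = 1)
  set.seed(31)
  mid <- which.min(abs(pr$wavelengths - 1300))
  a <- vapply(times, function(t)
    generate_spectrum(st, pr, hydrodynamic_state(400, 0.3), org,
                      seed = NULL)$absorbance[mid], numeric(1))
  fit <- summary(lm(a ~ times))$coefficients
  expect_gt(fit["times", "Pr(>|t|)"], 0.01)  # slope consistent with zero
})

test_that("spectra matrices are seed-deterministic", {
  org <- organism_heterolactic("cluster")
  d <- design_calibration_states(12, org, seed = 3)
  A <- generate_spectra_matrix(d, fast_probe(), hydrodynamic_state(400, 0.3),
                               org, seed = 4)
  B <- generate_spectra_matrix(d, fast_probe(), hydrodynamic_state(400, 0.3),
                               org, seed = 4)
  expect_identical(A, B)
})
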