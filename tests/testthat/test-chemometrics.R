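# chemometrics module: Norris derivative, screening, MLR, PLS, PRESS,
# prediction, statistics.

test_that("Norris second derivative annihilates affine baselines", {
  grid <- seq(1000, 1200, by = 2)
  spec <- pretreatment_spec("norris_d2", segment = 5, gap = 5)
  const <- rep(3, length(grid))
  lin <- 0.5 + 0.01 * grid
  expect_equal(max(abs(norris_second_derivative(const, spec,
                                                wavelengths = grid))), 0)
  expect_equal(max(abs(norris_second_derivative(lin, spec,
                                                wavelengths = grid))), 0,
               tolerance = 1e-12)
})

test_that("Norris derivative of a quadratic is the closed-form constant", {
  h <- 2; g <- 5; cc <- 3e-4
  grid <- seq(1000, 1300, by = h)
  for (seg in c(1, 5, 9)) {
    spec <- pretreatment_spec("norris_d2", segment = seg, gap = g)
    d2 <- norris_second_derivative(cc * grid^2, spec, wavelengths = grid)
    expect_equal(as.numeric(d2), rep(2 * cc * (g * h)^2, length(d2)),
                 tolerance = 1e-9)
  }
  expect_error(norris_second_derivative(rep(1, 15),
                                        pretreatment_spec("norris_d2")),
               "too short")
})

test_that("trimmed grid annotation matches the dropped edges", {
  grid <- seq(1000, 1100, by = 2)
  spec <- pretreatment_spec("norris_d2", segment = 5, gap = 5)
  d2 <- norris_second_derivative(sin(grid / 20), spec, wavelengths = grid)
  reach <- 5 + 2  # gap + (segment-1)/2
  expect_equal(attr(d2, "wavelengths"),
               grid[(reach + 1):(length(grid) - reach)])
})

test_that("screen passes clean sets and catches a constructed outlier", {
  X <- latent_matrix(50, 30, k = 3, noise = 1e-3, seed = 2)
  scr <- pca_mahalanobis_screen(X)
  expect_length(scr$outliers, 0)
  # displace one sample 10 pooled sds along PC1
  sv <- svd(scale(X, scale = FALSE))
  dir1 <- sv$v[, 1]
  X2 <- X
  X2[7, ] <- X2[7, ] + 10 * sd(sv$u[, 1] * sv$d[1]) * dir1
  scr2 <- pca_mahalanobis_screen(X2)
  expect_identical(scr2$outliers, 7L)
  expect_error(pca_mahalanobis_screen(matrix(1, 12, 5)), "zero variance")
})

test_that("flagged fraction matches the chi-square tail for 3 PCs", {
  X <- latent_matrix(10000, 10, k = 3, noise = 1e-7, seed = 4)
  scr <- pca_mahalanobis_screen(X, md_limit = 3)
  expect_equal(scr$n_components, 3)
  frac <- length(scr$outliers) / nrow(X)
  p_tail <- pchisq(9, df = 3, lower.tail = FALSE)  # 0.0293
  expect_gt(frac, 0.5 * p_tail)
  expect_lt(frac, 2 * p_tail)
  expect_equal(scr$chisq95, qchisq(0.95, 3))
})

test_that("MLR recovers exact and noisy linear relations and guards df", {
  set.seed(5)
  X <- matrix(runif(45 * 19, 0, 2), 45, 19)
  y <- drop(X %*% seq(0.1, 1.9, by = 0.1)) + 3
  m <- fit_mlr(X, y)
  expect_equal(m$training_stats$R2, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  # noisy single-channel relation: recovered slope within 3 sds
  y2 <- 2 * X[, 7] + 5 + rnorm(45, sd = 0.1)
  m2 <- fit_mlr(X, y2)
  se <- sqrt(diag(solve(crossprod(cbind(1, X)))))[8] * 0.1
  expect_lt(abs(m2$coefficients[7] - 2), 3 * se)
  expect_error(fit_mlr(X[1:20, ], y[1:20]), "n > p \\+ 1")
  expect_error(fit_mlr(cbind(X[, 1], X[, 1], X[, 1:17]), y),
               "rank-deficient")
})

test_that("PLS: rank-1 exact fit, OLS limit at full rank, order invariance", {
  set.seed(6)
  # rank-1 X, y exactly linear in it: one factor suffices
  t1 <- rnorm(20); p1 <- runif(8)
  X1 <- t1 %*% t(p1)
  y1 <- 2 * t1
  m1 <- fit_pls(X1, y1, n_factors = 1)
  expect_lt(max(abs(predict(m1, X1) - y1)), 1e-10)
  # full-rank tall X: f = rank(X) reproduces OLS predictions
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(30, sd = 0.3)
  mp <- fit_pls(X, y, n_factors = 5)
  ols <- lm.fit(cbind(1, X), y)$fitted.values
  expect_lt(max(abs(predict(mp, X) - ols)) / max(abs(ols)), 1e-8)
  # permutation invariance of coefficients
  ix <- sample(30)
  mq <- fit_pls(X[ix, ], y[ix], n_factors = 3)
  mr <- fit_pls(X, y, n_factors = 3)
  expect_equal(mq$coefficients, mr$coefficients, tolerance = 1e-10)
})

test_that("PRESS equals a brute-force per-sample refit loop and picks rank", {
  set.seed(7)
  n <- 16; p <- 8
  T_ <- matrix(rnorm(n * 2), n, 2)
  X <- T_ %*% matrix(rnorm(2 * p), 2, p)
  X <- X + 1e-9 * matrix(rnorm(n * p), n, p)
  y <- drop(T_ %*% c(2, -1))
  sel <- press_select(X, y, max_factors = 5)
  expect_equal(sel$n_factors, 2)          # noiseless rank-2 relation
  expect_lte(sel$n_factors, 5)
  # independent LOO oracle: refit fit_pls n times per factor count
  press_oracle <- sapply(1:5, function(f) {
    sum(sapply(seq_len(n), function(i) {
      m <- fit_pls(X[-i, ], y[-i], n_factors = f)
      (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }))
  })
  expect_equal(unname(sel$PRESS), unname(press_oracle), tolerance = 1e-10)
  expect_equal(sel$SECV, sqrt(sel$PRESS / n))
  expect_error(press_select(X, y, max_factors = 15), "too large")
})

test_that("norris_d2 models are invariant to affine baselines at predict", {
  cfg <- fast_hetero_cfg(seed = 11)
  m <- build_calibration(cfg, "glucose")
  org <- cfg$organism
  pr <- cfg$instrument; pr$photometric_noise_sd <- 0
  sp <- generate_spectrum(broth_state(25, lactate = 10, acetate = 5,
                                      biomass = 6), pr,
                          cfg$hydro, org)
  raw <- sp$absorbance
  shifted <- raw + 0.4 + 1e-4 * pr$wavelengths
  p0 <- predict(m, structure(matrix(raw, 1), wavelengths = pr$wavelengths))
  p1 <- predict(m, structure(matrix(shifted, 1),
                             wavelengths = pr$wavelengths))
  expect_lt(abs(p1 - p0), 1e-6)
  # blank (water-only) spectrum predicts glucose near zero
  blank <- generate_spectrum(broth_state(0), pr, hydrodynamic_state(0, 0),
                             org)
  pb <- predict(m, blank)
  expect_lt(abs(pb), 3 * m$training_stats$SEC + 1)
  expect_error(predict(m, matrix(0, 1, 5)), "grid mismatch")
})

test_that("calibration statistics match hand-checkable arithmetic", {
  st0 <- calibration_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st0$bias, 0); expect_equal(st0$RMSE, 0)
  expect_equal(st0$SEP, 0); expect_equal(st0$R2, 1)
  stc <- calibration_stats(c(3, 4, 5), c(1, 2, 3))
  expect_equal(stc$bias, 2); expect_equal(stc$RMSE, 2)
  expect_equal(stc$SEP, 0)  # constant offset is pure bias
  # worked 3-point case, frozen from independent arithmetic
  st <- calibration_stats(c(1.1, 1.9, 3.2), c(1, 2, 3))
  expect_equal(st$bias, 0.2 / 3)
  expect_equal(st$RMSE, sqrt(0.06 / 3))
  expect_equal(st$SEP, sqrt(0.0466666666666667 / 2), tolerance = 1e-12)
  # bias-correction identity: SEP^2 <= RMSEP^2 * n/(n-1)
  expect_lte(st$SEP^2, st$RMSE^2 * 3 / 2 + 1e-12)
  expect_error(calibration_stats(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibration_stats(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("paired NIR-vs-lab t test matches the closed form", {
  expect_equal(paired_nir_lab_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2, p = 1))
  # differences (1, 2, 3): t = mean/(sd/sqrt(3)) = 2*sqrt(3)
  res <- paired_nir_lab_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3))
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2))
  expect_equal(paired_nir_lab_test(c(2, 3), c(1, 2))$p, 0)  # constant diff
  expect_error(paired_nir_lab_test(1, 1), "at least 2")
})
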