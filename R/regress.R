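# Calibration regressions: MLR on discrete filter channels, NIPALS PLS1
# on pretreated full spectra, and leave-one-out PRESS factor selection.

new_calibration_model <- function(method, analyte, coefficients, intercept,
                                  input_wavelengths, used_idx, pretreatment,
                                  n_factors = NULL, pls = NULL,
                                  training_range = NULL, y_mean = NULL,
                                  training_stats = NULL, organism = NULL,
                                  chromophore_id = NULL, instrument = NULL,
                                  scatter_coefficient = NULL) {
  structure(list(method = method, analyte = analyte,
                 coefficients = coefficients, intercept = intercept,
                 input_wavelengths = input_wavelengths, used_idx = used_idx,
                 pretreatment = pretreatment, n_factors = n_factors,
                 pls = pls, training_range = training_range,
                 y_mean = y_mean, training_stats = training_stats,
                 organism = organism, chromophore_id = chromophore_id,
                 instrument = instrument,
                 scatter_coefficient = scatter_coefficient),
            class = "calibration_model")
}

#' Multiple linear regression calibration
#'
#' Ordinary least squares of the reference concentration on all filter
#' absorbances plus an intercept. Refuses under-determined (`n <= p + 1`)
#' or rank-deficient designs rather than silently pseudo-inverting.
#'
#' @param X absorbance matrix, n samples x p channels (p = 19 for the
#'   filter instrument); a `wavelengths` attribute is used if present.
#' @param y reference concentrations, g/L.
#' @param analyte label.
#' @param wavelengths optional grid override.
#' @return a `calibration_model` with training statistics.
#' @export
fit_mlr <- function(X, y, analyte = "analyte", wavelengths = NULL) {
  X <- as.matrix(X)
  grid <- wavelengths %||% attr(X, "wavelengths") %||% seq_len(ncol(X))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_config("length(y) must equal nrow(X)")
  if (n <= p + 1L)
    stop_config("MLR needs n > p + 1 (got n = ", n, ", p = ", p, ")")
  Xi <- cbind(1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi))
    stop_config("rank-deficient design (rank ", qrx$rank, " < ", ncol(Xi),
                "); refusing to pseudo-invert")
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xi %*% beta)
  stats <- calibration_stats(fitted, y, df_model = p)
  new_calibration_model(
    method = "MLR", analyte = analyte, coefficients = beta[-1L],
    intercept = beta[1L], input_wavelengths = grid,
    used_idx = seq_len(p), pretreatment = pretreatment_spec("none"),
    training_range = range(y), y_mean = mean(y), training_stats = stats)
}

# NIPALS PLS1 on centered data. Returns per-factor weights W, loadings P,
# y-loadings q, and the cumulative coefficient matrix B (p x nf): column f
# holds the regression vector using factors 1..f. Extraction stops early
# if X is deflated to (numerical) zero; the realized factor count is nf_out.
nipals_pls1 <- function(Xc, yc, nf) {
  p <- ncol(Xc)
  W <- matrix(0, p, nf); P <- matrix(0, p, nf); q <- numeric(nf)
  B <- matrix(0, p, nf)
  f_out <- 0L
  for (f in seq_len(nf)) {
    w <- crossprod(Xc, yc)  # p x 1
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12) break
    w <- w / nw
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-24) break
    pl <- crossprod(Xc, t_sc) / tt
    qf <- sum(yc * t_sc) / tt
    Xc <- Xc - t_sc %*% t(pl)
    yc <- yc - qf * t_sc
    W[, f] <- w; P[, f] <- pl; q[f] <- qf
    f_out <- f
    Wf <- W[, seq_len(f), drop = FALSE]
    Pf <- P[, seq_len(f), drop = FALSE]
    R <- crossprod(Pf, Wf)  # f x f, upper triangular in exact arithmetic
    B[, f] <- Wf %*% solve(R, q[seq_len(f)])
  }
  if (f_out == 0L) stop("PLS: X carries no covariance with y")
  if (f_out < nf) for (f in (f_out + 1L):nf) B[, f] <- B[, f_out]
  list(W = W[, seq_len(f_out), drop = FALSE],
       P = P[, seq_len(f_out), drop = FALSE], q = q[seq_len(f_out)],
       B = B, n_factors = f_out)
}

#' NIPALS PLS1 calibration
#'
#' Partial least squares regression with a single response, built by
#' NIPALS factor extraction with deflation. Centered in both X and y;
#' fully deterministic and invariant to sample order.
#'
#' @param X pretreated spectra matrix (n x p).
#' @param y reference concentrations, g/L.
#' @param n_factors number of latent factors, `1 <= n_factors <=
#'   min(n - 1, p)`. If X runs out of rank earlier, the realized factor
#'   count is reported in the model.
#' @param analyte label.
#' @param wavelengths optional grid override.
#' @return a `calibration_model` with training statistics (SEC computed
#'   with `n - n_factors - 1` degrees of freedom).
#' @export
fit_pls <- function(X, y, n_factors, analyte = "analyte",
                    wavelengths = NULL) {
  X <- as.matrix(X)
  grid <- wavelengths %||% attr(X, "wavelengths") %||% seq_len(ncol(X))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_config("length(y) must equal nrow(X)")
  check_number(n_factors, "n_factors", lower = 1, upper = min(n - 1, p))
  n_factors <- as.integer(n_factors)
  x_mean <- colMeans(X); y_mean <- mean(y)
  fit <- nipals_pls1(sweep(X, 2L, x_mean), y - y_mean, n_factors)
  nf <- min(n_factors, fit$n_factors)
  b <- fit$B[, nf]
  fitted <- drop(sweep(X, 2L, x_mean) %*% b) + y_mean
  stats <- calibration_stats(fitted, y, df_model = nf)
  new_calibration_model(
    method = "PLS", analyte = analyte, coefficients = b,
    intercept = y_mean - sum(x_mean * b), input_wavelengths = grid,
    used_idx = seq_len(p), pretreatment = pretreatment_spec("none"),
    n_factors = nf,
    pls = list(W = fit$W, P = fit$P, q = fit$q, x_mean = x_mean,
               y_mean = y_mean),
    training_range = range(y), y_mean = y_mean, training_stats = stats)
}

#' PRESS-based PLS factor selection
#'
#' Cross-validated predictive residual error sum of squares,
#' `PRESS(f) = sum_i (y_i - yhat_{i,-i}(f))^2`, with true refits per
#' held-out sample (leave-one-out by default, k-fold selectable). The
#' selected factor count is the smallest `f` attaining the minimum
#' PRESS; `SECV(f) = sqrt(PRESS(f)/n)`.
#'
#' @param X pretreated spectra matrix.
#' @param y reference concentrations.
#' @param max_factors largest factor count examined
#'   (`<= min(n - 2, p)`).
#' @param cv `"loo"` or `"kfold"`.
#' @param k folds when `cv = "kfold"`.
#' @param seed seed for the k-fold shuffle (LOO is deterministic).
#' @return list with `n_factors` (selected), `PRESS`, `SECV`.
#' @export
press_select <- function(X, y, max_factors, cv = c("loo", "kfold"),
                         k = 10, seed = 1L) {
  cv <- match.arg(cv)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (max_factors > min(n - 2, p))
    stop_config("max_factors too large for n = ", n, ", p = ", p)
  max_factors <- as.integer(max_factors)
  folds <- if (cv == "loo") as.list(seq_len(n)) else {
    idx <- with_seed(seed, sample(n))
    split(idx, rep_len(seq_len(k), n))
  }
  press <- numeric(max_factors)
  for (fold in folds) {
    Xt <- X[-fold, , drop = FALSE]; yt <- y[-fold]
    xm <- colMeans(Xt); ym <- mean(yt)
    fit <- nipals_pls1(sweep(Xt, 2L, xm), yt - ym, max_factors)
    Zv <- sweep(X[fold, , drop = FALSE], 2L, xm)
    pred <- Zv %*% fit$B + ym  # |fold| x max_factors
    press <- press + colSums((y[fold] - pred)^2)
  }
  # smallest factor count at the (numerically tied) minimum
  best <- min(which(press <= min(press) * (1 + 1e-8) + 1e-12))
  list(n_factors = best, PRESS = press, SECV = sqrt(press / n))
}

#' Predict concentrations from spectra
#'
#' Applies the model's pretreatment and channel mask internally, then
#' the stored regression vector. Predictions outside the training range
#' +/- 10% are flagged in the `out_of_range` attribute.
#'
#' @param object a `calibration_model`.
#' @param newdata spectra matrix on the model's instrument grid (raw,
#'   untreated), or a single spectrum vector / `nir_spectrum`.
#' @param ... unused.
#' @return numeric vector of predicted concentrations, g/L, with
#'   attribute `out_of_range`.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (inherits(newdata, "nir_spectrum")) {
    wl <- newdata$wavelengths
    newdata <- matrix(newdata$absorbance, nrow = 1L)
    attr(newdata, "wavelengths") <- wl
  }
  vec <- is.null(dim(newdata))
  if (vec) {
    wl <- attr(newdata, "wavelengths")
    newdata <- matrix(newdata, nrow = 1L)
    attr(newdata, "wavelengths") <- wl
  }
  grid <- attr(newdata, "wavelengths")
  if (!is.null(grid) &&
      !isTRUE(all.equal(as.numeric(grid),
                        as.numeric(object$input_wavelengths),
                        tolerance = 1e-8)))
    stop_config("wavelength grid mismatch between model and spectra")
  Z <- as.matrix(newdata)
  if (ncol(Z) != length(object$input_wavelengths))
    stop_config("wavelength grid mismatch: model expects ",
                length(object$input_wavelengths), " channels, got ", ncol(Z))
  if (object$pretreatment$kind == "norris_d2")
    Z <- norris_second_derivative(Z, object$pretreatment)
  Z <- Z[, object$used_idx, drop = FALSE]
  pred <- drop(Z %*% object$coefficients) + object$intercept
  rng <- object$training_range
  slack <- 0.1 * diff(rng)
  attr(pred, "out_of_range") <- pred < rng[1] - slack | pred > rng[2] + slack
  pred
}
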