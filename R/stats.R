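#' Calibration / validation error statistics
#'
#' The standard chemometric accuracy suite for a set of paired
#' predictions and reference values:
#' * `bias = mean(pred - ref)`
#' * `RMSE = sqrt(mean((pred - ref)^2))` (reported as RMSEC on a
#'   training set, RMSEP on a validation set)
#' * `SEP = sqrt(sum((e_i - bias)^2) / (n - 1))` - the bias-corrected
#'   standard error of prediction
#' * `SEC = sqrt(sum(e_i^2) / (n - df_model - 1))` - the standard error
#'   of calibration with `df_model` model degrees of freedom (19 for the
#'   filter MLR, the factor count for PLS)
#' * `R2` - squared Pearson correlation of prediction and reference.
#'
#' @param pred predicted concentrations, g/L.
#' @param ref reference concentrations, g/L.
#' @param df_model model degrees of freedom used for SEC (default 0).
#' @return an object of class `validation_stats`: list with `n`, `R2`,
#'   `bias`, `RMSE`, `SEP`, `SEC`, and `range` of the reference values.
#' @export
calibration_stats <- function(pred, ref, df_model = 0) {
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  n <- length(ref)
  if (length(pred) != n) stop_config("pred and ref must have equal length")
  if (n < 3) stop_config("need at least 3 pairs")
  if (stats::var(ref) < .Machine$double.eps)
    stop_config("zero variance in reference values: R2 undefined")
  e <- pred - ref
  bias <- mean(e)
  rmse <- sqrt(mean(e^2))
  sep <- sqrt(sum((e - bias)^2) / (n - 1))
  sec <- if (n - df_model - 1 > 0) sqrt(sum(e^2) / (n - df_model - 1))
         else NA_real_
  r2 <- stats::cor(pred, ref)^2
  structure(list(n = n, R2 = r2, bias = bias, RMSE = rmse, SEP = sep,
                 SEC = sec, df_model = df_model, range = range(ref)),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  range = %.2f-%.2f g/L  R2 = %.4f\n  RMSE = %.3f  SEP = %.3f  SEC = %.3f  bias = %+.3f g/L\n",
    x$n, x$range[1], x$range[2], x$R2, x$RMSE, x$SEP, x$SEC, x$bias))
  invisible(x)
}

#' Paired Student's t test between NIR predictions and lab references
#'
#' Classical paired t on the differences with a two-sided p value. The
#' degenerate case of zero-variance differences is handled explicitly:
#' identical pairs give `t = 0, p = 1`; a constant nonzero difference
#' gives `p = 0`.
#'
#' @param pred NIR-predicted concentrations.
#' @param ref reference-assay concentrations.
#' @return list with `t`, `df`, `p`.
#' @export
paired_nir_lab_test <- function(pred, ref) {
  d <- as.numeric(pred) - as.numeric(ref)
  n <- length(d)
  if (length(ref) != length(pred)) stop_config("unequal lengths")
  if (n < 2) stop_config("need at least 2 pairs")
  s <- stats::sd(d)
  if (s < .Machine$double.eps) {
    if (abs(mean(d)) < .Machine$double.eps)
      return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Residence time of the broth in the flow cell
#'
#' @param volume_mm3 flow cell volume, mm^3 (114 for the external-loop
#'   cell).
#' @param flow_mL_min circulation flow rate, mL/min (40 in the default
#'   loop).
#' @return residence time in seconds.
#' @export
flow_cell_residence_time <- function(volume_mm3 = 114, flow_mL_min = 40) {
  check_number(volume_mm3, "volume_mm3", lower = 0)
  check_number(flow_mL_min, "flow_mL_min", lower = .Machine$double.eps)
  (volume_mm3 / 1000) / flow_mL_min * 60
}
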