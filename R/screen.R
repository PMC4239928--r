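#' PCA / Mahalanobis-distance sample screening
#'
#' Screens a spectra matrix for outliers before calibration. PCA is run
#' on the centered spectra; principal components are retained up to
#' `retained_variance` of the total variance; each sample's Mahalanobis
#' distance is computed in score space and standardized by the number of
#' retained components (the chemometric "global H" statistic,
#' `GH = MD^2 / k`, with expectation 1 for a well-behaved sample).
#' Samples with `GH > md_limit` are flagged in a single pass; the 95%
#' chi-square quantile for `k` degrees of freedom is reported alongside
#' as a diagnostic.
#'
#' @param X spectra matrix, n samples x p channels (n >= 10).
#' @param md_limit flagging limit on `GH` (default 3, the conventional
#'   "3 sigma" screen).
#' @param retained_variance fraction of variance the retained PCs must
#'   explain (default 0.99).
#' @return list with `inliers`, `outliers` (row indices), `gh` (per
#'   sample), `n_components`, `scores`, `chisq95` (the 95% chi-square
#'   quantile of `MD^2` for `k` components, diagnostic only).
#' @export
pca_mahalanobis_screen <- function(X, md_limit = 3,
                                   retained_variance = 0.99) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop_config("need at least 10 samples to screen")
  if (!all(is.finite(X))) stop_config("non-finite values in spectra matrix")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (sum(Xc^2) < .Machine$double.eps)
    stop_config("degenerate spectra matrix: zero variance")
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (nrow(X) - 1)
  k <- which(cumsum(ev) / sum(ev) >= retained_variance)[1L]
  k <- max(1L, min(k, nrow(X) - 1L))
  scores <- Xc %*% sv$v[, seq_len(k), drop = FALSE]
  md2 <- rowSums(sweep(scores^2, 2L, ev[seq_len(k)], "/"))
  gh <- md2 / k
  out <- which(gh > md_limit)
  list(inliers = setdiff(seq_len(nrow(X)), out), outliers = out,
       gh = gh, n_components = k, scores = scores,
       chisq95 = stats::qchisq(0.95, df = k))
}
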