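#' Pretreatment specification
#'
#' @param kind `"none"` or `"norris_d2"` (gap-segment second derivative).
#' @param segment moving-average smoothing window, points (odd, >= 1).
#' @param gap derivative gap, points (>= 1).
#' @return an object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(kind = c("none", "norris_d2"), segment = 5,
                              gap = 5) {
  kind <- match.arg(kind)
  check_number(segment, "segment", lower = 1)
  check_number(gap, "gap", lower = 1)
  if (segment %% 2 != 1) stop_config("segment must be odd")
  structure(list(kind = kind, segment = as.integer(segment),
                 gap = as.integer(gap)),
            class = "pretreatment_spec")
}

#' Norris gap-segment second derivative
#'
#' Smooths each spectrum with a centered `segment`-point moving average
#' `s`, then forms the gap second difference
#' `d2(i) = s(i - gap) - 2 s(i) + s(i + gap)`. Edge points that lack a
#' full window are dropped; the returned matrix carries the trimmed grid
#' in its `wavelengths` attribute. The transform annihilates constant
#' and linear baselines exactly; a quadratic `c * lambda^2` on a uniform
#' grid of step `h` maps to the constant `2 c (gap h)^2`.
#'
#' @param X spectra matrix (samples x wavelengths) or a single spectrum
#'   vector; a `wavelengths` attribute is propagated if present.
#' @param spec a [pretreatment_spec()] with `kind = "norris_d2"`.
#' @param wavelengths optional grid override.
#' @return matrix (or vector) of second-difference values with attribute
#'   `wavelengths` (the trimmed grid).
#' @export
norris_second_derivative <- function(X, spec = pretreatment_spec("norris_d2"),
                                     wavelengths = NULL) {
  vec <- is.null(dim(X))
  grid <- wavelengths %||% attr(X, "wavelengths")
  if (vec) X <- matrix(X, nrow = 1L)
  p <- ncol(X)
  g <- spec$gap
  half <- (spec$segment - 1L) %/% 2L
  if (p <= 2L * (g + spec$segment))
    stop_config("spectrum too short (", p, " points) for gap ", g,
                ", segment ", spec$segment)
  # centered moving average, valid for columns (half+1)..(p-half)
  S <- X
  if (half > 0) {
    cs <- t(apply(cbind(0, X), 1L, cumsum))
    idx <- (half + 1L):(p - half)
    S <- (cs[, idx + half + 1L, drop = FALSE] -
            cs[, idx - half, drop = FALSE]) / spec$segment
    # S columns now correspond to original columns idx
    offset <- half
  } else offset <- 0L
  m <- ncol(S)
  keep <- (g + 1L):(m - g)
  D2 <- S[, keep - g, drop = FALSE] - 2 * S[, keep, drop = FALSE] +
    S[, keep + g, drop = FALSE]
  out_idx <- keep + offset  # indices into the original grid
  if (!is.null(grid)) attr(D2, "wavelengths") <- grid[out_idx]
  attr(D2, "index") <- out_idx
  if (vec) {
    v <- drop(D2)
    attr(v, "wavelengths") <- attr(D2, "wavelengths")
    attr(v, "index") <- out_idx
    return(v)
  }
  D2
}

# indices (into the original grid) of d2 output channels whose window
# touches any of the given bad input channels
d2_channels_touching <- function(bad_idx, p, spec) {
  half <- (spec$segment - 1L) %/% 2L
  reach <- spec$gap + half
  touched <- rep(FALSE, p)
  for (b in bad_idx) {
    lo <- max(1L, b - reach); hi <- min(p, b + reach)
    touched[lo:hi] <- TRUE
  }
  which(touched)
}
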