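# Internal helpers: argument validation, deterministic seed derivation,
# and a tiny stable string hash used for config fingerprints.

stop_config <- function(...) {
  cond <- structure(
    class = c("nirferm_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  stop(cond)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_config(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_config(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit over the UTF-8 bytes of a string; arithmetic kept in doubles
# (exact below 2^53) and reduced mod 2^32 after each step.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)   # xor touches the low byte only
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (lo16 * prime + ((hi16 * prime) %% 65536) * 65536) %% 2^32
  }
  h
}

#' Derive a stage seed from a root seed
#'
#' All randomness in a study flows from one root seed; each pipeline stage
#' (design, spectra, assays, validation, ...) gets its own stream derived
#' deterministically so that stages can be re-run independently.
#'
#' @param root integer root seed.
#' @param stage character stage label.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
seed_split <- function(root, stage) {
  check_number(root, "root")
  h <- fnv1a32(paste0(format(root, scientific = FALSE), "/", stage))
  as.integer(h %% (2^31 - 2)) + 1L
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
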