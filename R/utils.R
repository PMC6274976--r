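# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`, so
#' package internals never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic derived seed, kept strictly below 2^31 - 1. Used so that one
# master seed drives folds, per-fold classifiers, bootstrap resamples and
# null-subset draws without collisions.
mix_seed <- function(seed, a, b = 0L) {
  s <- (as.double(seed) %% 1000003) * 7919 + as.double(a) * 104729 +
    as.double(b) * 13007 + 17
  as.integer(s %% 2147483629)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Shortest decimal string that parses back to exactly `x`; used wherever
# thresholds or expression values must survive a text round trip.
num_to_string <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
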