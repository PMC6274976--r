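#' Chao-Shen-corrected Shannon entropy of a count profile
#'
#' Coverage-adjusted entropy estimator for undersampled count distributions.
#' With total count \eqn{n}, singleton count \eqn{f_1}, estimated coverage
#' \eqn{\hat C = 1 - f_1/n} (with the standard fix \eqn{\hat C = 1 - (n-1)/n}
#' when every observation is a singleton), and coverage-adjusted proportions
#' \eqn{\tilde p_i = \hat C \, c_i / n}, the estimate is the
#' Horvitz-Thompson-corrected sum
#' \deqn{\hat H = -\sum_{c_i > 0} \frac{\tilde p_i \log_2 \tilde p_i}
#'   {1 - (1 - \tilde p_i)^n}.}
#' Units are bits (base-2 logarithm throughout).
#'
#' @param counts Non-negative integer counts, one per facet; at least one
#'   must be positive.
#' @return An object of class `entropy_result`: a list with `entropy_bits`,
#'   `coverage`, `n` (total count), `f1` (number of singletons), and
#'   `specificity` (`1 - H / log2(K)` clamped to `[0, 1]`, defined as 1 when
#'   `K = 1`).
#' @examples
#' chao_shen_entropy(c(10, 10, 10, 10))$entropy_bits # ~2 bits
#' chao_shen_entropy(c(5, 0, 0))$entropy_bits        # 0 bits
#' @export
chao_shen_entropy <- function(counts) {
  if (length(counts) < 1) stopf("chao_shen_entropy: empty profile")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("chao_shen_entropy: counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stopf("chao_shen_entropy: counts must be integers (see integerize_cpm)")
  }
  counts <- round(counts)
  n <- sum(counts)
  if (n == 0) stopf("chao_shen_entropy: all-zero profile")
  f1 <- sum(counts == 1)
  coverage <- if (f1 == n) 1 - (n - 1) / n else 1 - f1 / n
  k <- length(counts)
  pos <- counts[counts > 0]
  p <- coverage * pos / n
  # p > 0 always here (coverage > 0 by the f1 == n fix)
  h <- -sum(p * log2(p) / (1 - (1 - p)^n))
  spec <- if (k == 1) 1 else clamp01(1 - h / log2(k))
  structure(
    list(entropy_bits = h, coverage = coverage, n = n, f1 = f1,
         specificity = spec),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("entropy %.4f bits | coverage %.4f | n %d | specificity %.4f\n",
              x$entropy_bits, x$coverage, x$n, x$specificity))
  invisible(x)
}

#' Convert a real-valued CPM profile to integer counts
#'
#' The coverage correction needs singleton counts, which are undefined for
#' real values, so CPM profiles are rounded elementwise. If rounding
#' annihilates a profile that had some expression, the largest facet is
#' rescued with a count of 1 so the entropy stays defined.
#'
#' @param cpm Non-negative finite numeric vector.
#' @return Integer vector of the same length.
#' @export
integerize_cpm <- function(cpm) {
  if (any(!is.finite(cpm))) stopf("integerize_cpm: non-finite CPM")
  if (any(cpm < 0)) stopf("integerize_cpm: negative CPM")
  counts <- round(cpm)
  if (all(counts == 0) && any(cpm > 0)) {
    counts[which.max(cpm)] <- 1
  }
  as.integer(counts)
}

#' Expression-specificity score of a CPM profile
#'
#' One minus the normalized Chao-Shen entropy of the (integerized) profile:
#' 1 means expression confined to a single facet, 0 means perfectly even
#' expression across all `K` facets. For `K = 1` the score is defined as 1.
#'
#' @param cpm Non-negative finite CPM values across facets (numeric vector).
#' @return A single number in `[0, 1]`.
#' @examples
#' expression_specificity(c(100, 0, 0, 0))  # 1
#' expression_specificity(c(20, 20, 0, 0))  # ~0.5
#' @export
expression_specificity <- function(cpm) {
  if (length(cpm) == 1) {
    if (!is.finite(cpm) || cpm < 0) stopf("expression_specificity: invalid CPM")
    if (cpm == 0) stopf("expression_specificity: all-zero profile")
    return(1)
  }
  counts <- integerize_cpm(cpm)
  if (sum(counts) == 0) stopf("expression_specificity: all-zero profile")
  chao_shen_entropy(counts)$specificity
}

#' Entropy and specificity for each row of a CPM matrix
#'
#' Convenience wrapper used by the CLI `specificity` subcommand: computes the
#' Chao-Shen entropy and the derived specificity score per row (gene).
#'
#' @param cpm Numeric matrix or data frame, genes in rows, facets in columns.
#' @return A data frame with columns `entropy_bits` and `specificity`.
#' @export
specificity_table <- function(cpm) {
  cpm <- as.matrix(cpm)
  res <- apply(cpm, 1, function(row) {
    er <- chao_shen_entropy(integerize_cpm(row))
    c(er$entropy_bits, er$specificity)
  })
  data.frame(entropy_bits = res[1, ], specificity = res[2, ])
}
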