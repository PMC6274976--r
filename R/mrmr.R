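#' Discretization settings for mRMR
#'
#' Continuous features are reduced to three states around the per-feature
#' mean: above `mean + alpha * sd`, below `mean - alpha * sd`, or in between
#' (`sd` is the population standard deviation). This mirrors the common
#' preprocessing of mutual-information-based feature rankers for continuous
#' data.
#'
#' @param alpha Positive threshold multiplier (default 1).
#' @return A list of class `discretization_spec`.
#' @export
discretization_spec <- function(alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stopf("discretization_spec: alpha must be a positive number")
  }
  structure(list(alpha = alpha, n_states = 3L), class = "discretization_spec")
}

#' Discretize a numeric vector into three states
#'
#' @param values Finite numeric vector, length >= 2.
#' @param spec A [discretization_spec()].
#' @return Integer vector of states in `{-1, 0, +1}`. A constant vector maps
#'   to all zeros.
#' @examples
#' discretize(c(0, 0, 0, 100)) # 0 0 0 1
#' @export
discretize <- function(values, spec = discretization_spec()) {
  if (length(values) < 2) stopf("discretize: need at least 2 values")
  if (any(!is.finite(values))) stopf("discretize: non-finite values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population sd
  st <- integer(length(values))
  if (s > 0) {
    st[values > m + spec$alpha * s] <- 1L
    st[values < m - spec$alpha * s] <- -1L
  }
  st
}

#' Mutual information between two discrete vectors (bits)
#'
#' \eqn{I = \sum_{a,b} p(a,b) \log_2 [p(a,b) / (p(a) p(b))]} over observed
#' state pairs, with \eqn{0 \log 0 = 0}.
#'
#' @param x,y Discrete vectors of equal length (any atomic type).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("mutual_information: length mismatch")
  if (length(x) == 0) stopf("mutual_information: empty vectors")
  xi <- match(x, unique(x))
  yi <- match(y, unique(y))
  nx <- max(xi)
  ny <- max(yi)
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ny + yi, nx * ny) / n
  px <- tabulate(xi, nx) / n
  py <- tabulate(yi, ny) / n
  outer_p <- rep(px, each = ny) * rep.int(py, nx)  # x-major, matching joint
  keep <- joint > 0
  max(0, sum(joint[keep] * log2(joint[keep] / outer_p[keep])))
}

rank_result <- function(order, scores, criterion, feature_names) {
  structure(
    list(order = as.integer(order), scores = as.numeric(scores),
         criterion = criterion, feature_names = feature_names[order]),
    class = "ranked_features"
  )
}

#' @export
print.ranked_features <- function(x, n = 10, ...) {
  cat(sprintf("%s feature ranking (%d features)\n", x$criterion,
              length(x$order)))
  k <- min(n, length(x$order))
  for (i in seq_len(k)) {
    cat(sprintf("  %2d. %s (%.4f)\n", i, x$feature_names[i], x$scores[i]))
  }
  if (length(x$order) > k) cat("  ...\n")
  invisible(x)
}

# Discretized design matrix + class states shared by both rankers.
mrmr_prepare <- function(table, spec) {
  if (n_features(table) < 1) stopf("ranking: table has no features")
  if (length(unique(table$labels)) < 2) {
    stopf("ranking: both classes must be present")
  }
  disc <- apply(table$values, 2, discretize, spec = spec)
  disc <- matrix(as.integer(disc), nrow = n_samples(table))
  y <- ifelse(table$labels == "positive", 1L, 0L)
  rel <- vapply(seq_len(ncol(disc)),
                function(j) mutual_information(disc[, j], y), numeric(1))
  list(disc = disc, rel = rel)
}

#' mRMR feature ranking (minimum redundancy, maximum relevance)
#'
#' Greedy ranking: the first feature maximizes mutual information with the
#' class; each subsequent feature maximizes, over the not-yet-selected
#' features \eqn{f},
#' \eqn{I(f;\,\mathrm{class}) - \frac{1}{|S|} \sum_{s \in S} I(f; f_s)}
#' (the MID "difference" scheme; `scheme = "MIQ"` divides instead). All
#' features, and the two-state class, enter mutual information after
#' three-state discretization. Greedy ties break toward the smaller original
#' column index.
#'
#' @param table A [feature_table()] with both classes present.
#' @param spec A [discretization_spec()].
#' @param scheme `"MID"` (default, difference) or `"MIQ"` (quotient).
#' @return A `ranked_features` object: `order` (permutation of feature
#'   indices), `scores` (criterion value at selection time), `criterion`,
#'   and `feature_names` in ranked order.
#' @export
mrmr_rank <- function(table, spec = discretization_spec(), scheme = "MID") {
  scheme <- match.arg(scheme, c("MID", "MIQ"))
  prep <- mrmr_prepare(table, spec)
  nfeat <- ncol(prep$disc)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(nfeat)   # running sum of MI against selected features
  remaining <- seq_len(nfeat)
  while (length(remaining) > 0) {
    if (length(selected) == 0) {
      sc <- prep$rel[remaining]
    } else {
      red_mean <- red_sum[remaining] / length(selected)
      sc <- if (scheme == "MID") {
        prep$rel[remaining] - red_mean
      } else {
        prep$rel[remaining] / pmax(red_mean, .Machine$double.eps)
      }
    }
    best <- remaining[which.max(sc)]  # which.max: first max = smallest index
    selected <- c(selected, best)
    scores <- c(scores, sc[which.max(sc)])
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0) {
      for (j in remaining) {
        red_sum[j] <- red_sum[j] +
          mutual_information(prep$disc[, j], prep$disc[, best])
      }
    }
  }
  rank_result(selected, scores, "mrmr", table$feature_names)
}

#' MaxRel feature ranking (relevance only)
#'
#' Features sorted by descending mutual information with the class, with no
#' redundancy penalty; ties break toward the smaller original column index.
#' The first element always coincides with the first element of
#' [mrmr_rank()].
#'
#' @inheritParams mrmr_rank
#' @return A `ranked_features` object with `criterion = "maxrel"`.
#' @export
maxrel_rank <- function(table, spec = discretization_spec()) {
  prep <- mrmr_prepare(table, spec)
  ord <- order(-prep$rel, seq_along(prep$rel))
  rank_result(ord, prep$rel[ord], "maxrel", table$feature_names)
}

#' Write a ranked feature list as TSV
#'
#' Emits `rank`, `feature`, `score` columns (1-based ranks).
#'
#' @param ranking A `ranked_features` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   feature = ranking$feature_names,
                   score = ranking$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
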