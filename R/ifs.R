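#' Incremental feature selection over a ranked feature list
#'
#' For each prefix size `i`, cross-validates the classifier on the table
#' restricted to the first `i` features of `ranking`, producing the IFS
#' curve (subset size versus SN/SP/ACC/MCC). The cross-validation partition
#' is computed once from `seed` and held fixed across all sizes so the curve
#' varies only through the feature subsets.
#'
#' @param table A [feature_table()].
#' @param ranking A `ranked_features` object over the table's features (a
#'   permutation of all feature indices).
#' @param spec A [classifier_spec()].
#' @param k Fold count (default 10).
#' @param seed Integer master seed.
#' @param max_size Largest prefix evaluated (default all features).
#' @param sizes Optional explicit vector of strictly increasing prefix
#'   sizes (overrides `max_size`; used by the pipeline's stride option).
#' @return An `ifs_curve`: a data frame with columns `i`, `SN`, `SP`, `ACC`,
#'   `MCC` and attribute `classifier`.
#' @export
run_ifs <- function(table, ranking, spec, k = 10L, seed = 1L,
                    max_size = NULL, sizes = NULL) {
  N <- n_features(table)
  if (length(ranking$order) != N || !setequal(ranking$order, seq_len(N))) {
    stopf("run_ifs: ranking must be a permutation of the table's %d features", N)
  }
  if (is.null(sizes)) {
    max_size <- max_size %||% N
    if (max_size > N) stopf("run_ifs: max_size exceeds %d features", N)
    sizes <- seq_len(max_size)
  }
  if (any(diff(sizes) <= 0) || any(sizes < 1) || any(sizes > N)) {
    stopf("run_ifs: sizes must be strictly increasing within 1..%d", N)
  }
  folds <- stratified_folds(table$labels, k, mix_seed(seed, 0L))
  rows <- lapply(sizes, function(i) {
    sub <- select_features(table, ranking$order[seq_len(i)])
    ms <- tryCatch(
      cross_validate(sub, spec, k = k, seed = seed, folds = folds),
      error = function(e) {
        stopf("run_ifs: CV failed at subset size %d: %s", i,
              conditionMessage(e))
      })
    data.frame(i = i, SN = ms$SN, SP = ms$SP, ACC = ms$ACC, MCC = ms$MCC)
  })
  curve <- do.call(rbind, rows)
  attr(curve, "classifier") <- spec
  class(curve) <- c("ifs_curve", "data.frame")
  curve
}

#' Best point of an IFS curve
#'
#' The point with maximal MCC; ties resolve to the smallest subset size.
#'
#' @param curve An `ifs_curve` from [run_ifs()].
#' @return A list with `size` and `metrics` (one-row data frame).
#' @export
optimal_point <- function(curve) {
  if (nrow(curve) == 0) stopf("optimal_point: empty curve")
  best <- which.max(curve$MCC)  # first maximum = smallest size
  list(size = curve$i[best], metrics = curve[best, , drop = FALSE])
}

#' First subset size whose MCC reaches a threshold
#'
#' @param curve An `ifs_curve`.
#' @param threshold MCC threshold.
#' @return Smallest `i` with `MCC >= threshold`, or `NA` if never reached.
#' @export
first_crossing <- function(curve, threshold) {
  if (nrow(curve) == 0) stopf("first_crossing: empty curve")
  hit <- which(curve$MCC >= threshold)
  if (length(hit) == 0) NA_integer_ else curve$i[hit[1]]
}

#' Randomized-feature-subset null distribution of the MCC
#'
#' Builds `n_iter` feature subsets of size `subset_size`, each containing
#' the anchor feature (the expression-specificity column in the original
#' analysis) plus `subset_size - 1` features sampled uniformly without
#' replacement from the rest, cross-validates the classifier on each, and
#' collects the MCCs. The CV partition and classifier seed are held fixed
#' across iterations so only the subsets vary.
#'
#' @param table A [feature_table()].
#' @param anchor Feature name present in every subset.
#' @param subset_size Total subset size (>= 2, <= number of features).
#' @param spec A [classifier_spec()].
#' @param n_iter Number of random subsets (the original analysis used 1000).
#' @param k Fold count.
#' @param seed Integer master seed.
#' @return A `null_distribution`: list with `mccs`, `mean`, `sd` (sample
#'   standard deviation), `anchor_feature`, `subset_size`, `seed`.
#' @export
random_subset_null <- function(table, anchor, subset_size, spec,
                               n_iter = 1000L, k = 10L, seed = 1L) {
  N <- n_features(table)
  a <- match(anchor, table$feature_names)
  if (is.na(a)) stopf("random_subset_null: no feature named '%s'", anchor)
  if (subset_size < 2) stopf("random_subset_null: subset_size must be >= 2")
  if (subset_size > N) stopf("random_subset_null: subset_size exceeds %d", N)
  if (n_iter < 1) stopf("random_subset_null: n_iter must be >= 1")
  folds <- stratified_folds(table$labels, k, mix_seed(seed, 0L))
  others <- setdiff(seq_len(N), a)
  mccs <- vapply(seq_len(n_iter), function(it) {
    pick <- with_seed(mix_seed(seed, it, 1L),
                      sample(others, subset_size - 1L))
    subset <- sort(c(a, pick))  # column order fixed; classifier must not care
    sub <- select_features(table, subset)
    cross_validate(sub, spec, k = k, seed = seed, folds = folds)$MCC
  }, numeric(1))
  structure(
    list(mccs = mccs, mean = mean(mccs), sd = stats::sd(mccs),
         anchor_feature = anchor, subset_size = as.integer(subset_size),
         seed = as.integer(seed)),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null MCC distribution: %d subsets of size %d anchored on '%s'\n",
    length(x$mccs), x$subset_size, x$anchor_feature))
  cat(sprintf("  mean %.4f  sd %.4f\n", x$mean, x$sd))
  invisible(x)
}

#' Standardized excess of an observed MCC over the null
#'
#' `(observed - mean) / sd` against a [random_subset_null()] distribution.
#' In the original analysis an observed 0.880 against a null of mean 0.860
#' and sd 0.015 gives an excess of 1.33 standard deviations.
#'
#' @param observed_mcc Observed MCC.
#' @param null A `null_distribution`, or any list with `mean` and `sd`.
#' @return The signed number of null standard deviations.
#' @export
sigma_excess <- function(observed_mcc, null) {
  if (!is.finite(null$sd) || null$sd <= 0) {
    stopf("sigma_excess: undefined for null sd = 0")
  }
  (observed_mcc - null$mean) / null$sd
}

#' Five-number box-plot summary of a null distribution
#'
#' Quartiles (type-7), and whiskers at the most extreme values within
#' 1.5 IQR of the box, matching a standard box plot of the stored MCCs.
#'
#' @param null A `null_distribution`.
#' @return Named numeric vector: `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`.
#' @export
null_summary <- function(null) {
  q <- stats::quantile(null$mccs, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(null$mccs[null$mccs >= q[1] - 1.5 * iqr])
  hi <- max(null$mccs[null$mccs <= q[3] + 1.5 * iqr])
  c(lower_whisker = lo, q1 = q[1], median = q[2], q3 = q[3],
    upper_whisker = hi)
}

#' Write an IFS curve as TSV
#'
#' One row per subset size: `i`, `SN`, `SP`, `ACC`, `MCC`.
#'
#' @param curve An `ifs_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
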