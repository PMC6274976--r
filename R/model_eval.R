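#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp, tn, fp, fn)
  if (any(v < 0) || any(v != round(v))) {
    stopf("confusion_counts: counts must be non-negative integers")
  }
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' \deqn{SN = TP/(TP+FN),\quad SP = TN/(TN+FP),\quad
#'       ACC = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A zero SN/SP denominator yields 0 with a warning; a zero factor in the
#' MCC root yields MCC = 0.
#'
#' @param counts A [confusion_counts()].
#' @return A list of class `metric_set` with `SN`, `SP`, `ACC`, `MCC` and
#'   the input `counts`.
#' @examples
#' compute_metrics(confusion_counts(3, 4, 1, 2))$MCC # 10 / sqrt(600)
#' @export
compute_metrics <- function(counts) {
  tp <- as.double(counts$TP); tn <- as.double(counts$TN)
  fp <- as.double(counts$FP); fn <- as.double(counts$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stopf("compute_metrics: no samples")
  sn <- if (tp + fn == 0) {
    warning("SN undefined (no positive samples); reporting 0"); 0
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("SP undefined (no negative samples); reporting 0"); 0
  } else tn / (tn + fp)
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(list(SN = sn, SP = sp, ACC = acc, MCC = mcc, counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("SN %.4f  SP %.4f  ACC %.4f  MCC %.4f\n",
              x$SN, x$SP, x$ACC, x$MCC))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns every sample to one of `k` folds so that fold sizes differ by at
#' most one and each class is spread across folds as evenly as possible
#' (per-class counts differ by at most one between folds). Deterministic for
#' a fixed seed.
#'
#' @param labels Vector of class labels (any type), one per sample.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stopf("stratified_folds: k must be >= 2")
  n <- length(labels)
  assign <- integer(n)
  fold_sizes <- integer(k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stopf("stratified_folds: class '%s' has %d members, fewer than k = %d",
              cl, length(idx), k)
      }
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # remainder goes to the currently smallest folds (ties: lowest index)
      recipients <- order(fold_sizes, seq_len(k))[seq_len(extra)]
      per_fold <- rep(base, k)
      per_fold[recipients] <- per_fold[recipients] + 1L
      fold_of <- rep(seq_len(k), times = per_fold)
      assign[idx] <- fold_of
      fold_sizes <- fold_sizes + per_fold
    }
  })
  assign
}

#' Cross-validate a classifier on a feature table
#'
#' Trains on `k - 1` folds, predicts the held-out fold, pools the confusion
#' counts over all folds and reports a single [compute_metrics()] result (so
#' one SN/SP/ACC/MCC per configuration, not per-fold averages). Folds are
#' stratified by default; all stochastic components derive from the one
#' `seed`.
#'
#' @param table A [feature_table()] with both classes present.
#' @param spec A [classifier_spec()].
#' @param k Fold count (default 10).
#' @param seed Integer master seed.
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1..k`); when supplied, `seed` only drives the per-fold classifiers.
#' @param stratified Use stratified folds (default `TRUE`).
#' @return A `metric_set` on the pooled counts, with attribute
#'   `"fold_counts"` holding the per-fold confusion counts.
#' @export
cross_validate <- function(table, spec, k = 10L, seed = 1L, folds = NULL,
                           stratified = TRUE) {
  if (is.null(folds)) {
    folds <- if (stratified) {
      stratified_folds(table$labels, k, mix_seed(seed, 0L))
    } else {
      with_seed(mix_seed(seed, 0L),
                sample(rep_len(seq_len(k), n_samples(table))))
    }
  }
  k <- max(folds)
  tp <- tn <- fp <- fn <- 0L
  fold_counts <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    train_tab <- feature_table(table$ids[train_idx], table$labels[train_idx],
                               table$values[train_idx, , drop = FALSE],
                               table$feature_names, table$class_names)
    fold_spec <- spec
    fold_spec$seed <- mix_seed(seed, f)
    model <- tryCatch(train_classifier(train_tab, fold_spec),
                      error = function(e) {
                        stopf("cross_validate: fold %d training failed: %s",
                              f, conditionMessage(e))
                      })
    pred <- predict(model, table$values[test_idx, , drop = FALSE])
    truth <- table$labels[test_idx]
    cc <- confusion_counts(sum(pred == "positive" & truth == "positive"),
                           sum(pred == "negative" & truth == "negative"),
                           sum(pred == "positive" & truth == "negative"),
                           sum(pred == "negative" & truth == "positive"))
    fold_counts[[f]] <- cc
    tp <- tp + cc$TP; tn <- tn + cc$TN; fp <- fp + cc$FP; fn <- fn + cc$FN
  }
  res <- compute_metrics(confusion_counts(tp, tn, fp, fn))
  attr(res, "fold_counts") <- fold_counts
  res
}
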