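test_that("metric formulas on spot values", {
  perfect <- compute_metrics(confusion_counts(5, 5, 0, 0))
  expect_equal(unlist(perfect[c("SN", "SP", "ACC", "MCC")]),
               c(SN = 1, SP = 1, ACC = 1, MCC = 1))
  inverted <- compute_metrics(confusion_counts(0, 0, 5, 5))
  expect_equal(inverted$MCC, -1)
  m <- compute_metrics(confusion_counts(3, 4, 1, 2))
  expect_equal(m$MCC, 10 / sqrt(600))
  expect_equal(m$ACC, 0.7)
  expect_warning(compute_metrics(confusion_counts(0, 5, 0, 0)), "SN undefined")
})

test_that("metrics agree with the literal-formula oracle and symmetries", {
  set.seed(20)
  for (rep in 1:300) {
    cc <- as.list(sample(0:40, 4, replace = TRUE))
    if (sum(unlist(cc)) == 0) cc[[1]] <- 1
    m <- suppressWarnings(
      compute_metrics(confusion_counts(cc[[1]], cc[[2]], cc[[3]], cc[[4]])))
    o <- metrics_oracle(cc[[1]], cc[[2]], cc[[3]], cc[[4]])
    expect_equal(m$SN, o$SN)
    expect_equal(m$SP, o$SP)
    expect_equal(m$ACC, o$ACC)
    expect_equal(m$MCC, o$MCC, tolerance = 1e-12)
    # swap classes and predictions together: MCC invariant
    sw <- suppressWarnings(
      compute_metrics(confusion_counts(cc[[2]], cc[[1]], cc[[4]], cc[[3]])))
    expect_equal(sw$MCC, m$MCC, tolerance = 1e-12)
    # invert predictions: MCC antisymmetric
    inv <- suppressWarnings(
      compute_metrics(confusion_counts(cc[[4]], cc[[3]], cc[[2]], cc[[1]])))
    expect_equal(inv$MCC, -m$MCC, tolerance = 1e-12)
  }
})

test_that("stratified folds balance sizes and classes", {
  labels <- c(rep("positive", 10), rep("negative", 10))
  f <- stratified_folds(labels, 10, seed = 1)
  expect_true(all(table(f) == 2))
  expect_true(all(table(f, labels) == 1))
  expect_identical(f, stratified_folds(labels, 10, seed = 1))
  expect_false(identical(f, stratified_folds(labels, 10, seed = 2)))

  # the study's sample total: 9339 positives + 14,294 negatives, 10 folds
  big <- c(rep("positive", 9339), rep("negative", 14294))
  fb <- stratified_folds(big, 10, seed = 3)
  sizes <- as.integer(table(fb))
  expect_true(all(sizes %in% c(2363L, 2364L)))
  per_class <- table(fb, big)
  expect_lte(max(per_class[, 1]) - min(per_class[, 1]), 1)
  expect_lte(max(per_class[, 2]) - min(per_class[, 2]), 1)
  expect_error(stratified_folds(c("positive", rep("negative", 20)), 5),
               "fewer than k")
})

test_that("cross-validation is deterministic and pools fold counts", {
  tab <- margin_toy(n_pos = 30, n_neg = 45, seed = 6)
  spec <- classifier_spec("logistic", seed = 5)
  m1 <- cross_validate(tab, spec, k = 5, seed = 5)
  m2 <- cross_validate(tab, spec, k = 5, seed = 5)
  expect_equal(m1[c("SN", "SP", "ACC", "MCC")],
               m2[c("SN", "SP", "ACC", "MCC")])
  expect_equal(m1$MCC, 1)  # separable => perfect under any sane classifier

  # pooled ACC is the sample-size-weighted mean of per-fold accuracies
  fc <- attr(m1, "fold_counts")
  accs <- vapply(fc, function(cc) (cc$TP + cc$TN) /
                   (cc$TP + cc$TN + cc$FP + cc$FN), numeric(1))
  ns <- vapply(fc, function(cc) cc$TP + cc$TN + cc$FP + cc$FN, numeric(1))
  expect_equal(m1$ACC, sum(accs * ns) / sum(ns))
})

test_that("all five algorithms solve a separable problem under CV", {
  tab <- margin_toy(n_pos = 40, n_neg = 60, seed = 8)
  for (alg in c("random_forest", "one_nn", "linear_svm", "logistic",
                "ripper")) {
    spec <- classifier_spec(alg, params = list(B = 15), seed = 2)
    expect_equal(cross_validate(tab, spec, k = 5, seed = 2)$MCC, 1,
                 info = alg)
  }
})

test_that("1-NN predicts its own training points perfectly", {
  res <- generate_table(synthetic_spec(n_pos = 25, n_neg = 35, n_facets = 5,
                                       n_informative = 2, seed = 14))
  model <- train_classifier(res$table, classifier_spec("one_nn"))
  expect_equal(predict(model, res$table), res$table$labels)
})

test_that("a B = 1 forest with all features behaves like a single tree", {
  tab <- margin_toy(n_pos = 25, n_neg = 35, seed = 9)
  spec <- classifier_spec("random_forest", params = list(B = 1, m = 1),
                          seed = 4)
  model <- train_classifier(tab, spec)
  expect_equal(length(model$fit$forest), 1)
  pred <- predict(model, tab)
  expect_gte(mean(pred == tab$labels), 0.95)  # bootstrap may drop a point
})

test_that("forests reduce variance relative to single trees", {
  mccs <- vapply(1:10, function(s) {
    res <- generate_table(synthetic_spec(n_pos = 120, n_neg = 180,
                                         n_facets = 15, n_informative = 4,
                                         effect_log2 = 1.5, seed = 100 + s))
    one <- cross_validate(res$table,
                          classifier_spec("random_forest",
                                          params = list(B = 1), seed = s),
                          k = 5, seed = s)$MCC
    many <- cross_validate(res$table,
                           classifier_spec("random_forest",
                                           params = list(B = 40), seed = s),
                           k = 5, seed = s)$MCC
    many - one
  }, numeric(1))
  expect_gt(mean(mccs), 0)
})

test_that("unknown algorithms are rejected", {
  expect_error(classifier_spec("boosting"), "arg")
  expect_error(classifier_spec("random_forest", params = list(B = 0)), "B")
})
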