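make_ifs_fixture <- function(seed = 23) {
  res <- generate_table(synthetic_spec(n_pos = 60, n_neg = 90, n_facets = 8,
                                       n_informative = 3, effect_log2 = 3,
                                       seed = seed))
  list(table = res$table, ranking = mrmr_rank(res$table),
       spec = classifier_spec("logistic", seed = 2))
}

test_that("run_ifs evaluates nested prefixes with a fixed partition", {
  fx <- make_ifs_fixture()
  curve <- run_ifs(fx$table, fx$ranking, fx$spec, k = 5, seed = 3,
                   max_size = 6)
  expect_equal(curve$i, 1:6)
  expect_true(all(curve$MCC >= -1 & curve$MCC <= 1))
  # rerun is identical (determinism)
  curve2 <- run_ifs(fx$table, fx$ranking, fx$spec, k = 5, seed = 3,
                    max_size = 6)
  expect_equal(as.data.frame(curve), as.data.frame(curve2))
})

test_that("curve values do not depend on features after max_size", {
  fx <- make_ifs_fixture()
  r2 <- fx$ranking
  tail_idx <- 5:8
  r2$order[tail_idx] <- rev(r2$order[tail_idx])  # permute the unused tail
  c1 <- run_ifs(fx$table, fx$ranking, fx$spec, k = 5, seed = 3, max_size = 4)
  c2 <- run_ifs(fx$table, r2, fx$spec, k = 5, seed = 3, max_size = 4)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("single-feature table yields a single-point curve", {
  tab <- margin_toy(n_pos = 20, n_neg = 30, seed = 4)
  ranking <- maxrel_rank(tab)
  curve <- run_ifs(tab, ranking, classifier_spec("logistic"), k = 5, seed = 1)
  expect_equal(nrow(curve), 1)
})

test_that("optimal_point takes the max MCC, ties to fewer features", {
  curve <- structure(
    data.frame(i = 1:3, SN = 0, SP = 0, ACC = 0, MCC = c(0.5, 0.7, 0.7)),
    class = c("ifs_curve", "data.frame"))
  expect_equal(optimal_point(curve)$size, 2)
  rising <- curve
  rising$MCC <- c(0.1, 0.2, 0.3)
  expect_equal(optimal_point(rising)$size, 3)
  set.seed(9)
  for (rep in 1:20) {
    rnd <- curve
    rnd$MCC <- runif(3)
    expect_equal(optimal_point(rnd)$metrics$MCC, max(rnd$MCC))
  }
})

test_that("first_crossing finds the earliest threshold hit", {
  curve <- structure(
    data.frame(i = 1:2, SN = 0, SP = 0, ACC = 0, MCC = c(0.2, 0.9)),
    class = c("ifs_curve", "data.frame"))
  expect_equal(first_crossing(curve, 0.88), 2)
  expect_true(is.na(first_crossing(curve, 1.1)))
  # monotone curves: crossing size is non-decreasing in the threshold
  set.seed(10)
  for (rep in 1:20) {
    mcc <- sort(runif(8))
    cv <- structure(
      data.frame(i = 1:8, SN = 0, SP = 0, ACC = 0, MCC = mcc),
      class = c("ifs_curve", "data.frame"))
    thr <- sort(runif(3))
    xs <- vapply(thr, function(t) {
      x <- first_crossing(cv, t)
      if (is.na(x)) 9L else x
    }, integer(1))
    expect_true(all(diff(xs) >= 0))
  }
  expect_lte(first_crossing(curve, max(curve$MCC)), optimal_point(curve)$size)
})

test_that("random_subset_null anchors subsets and is reproducible", {
  fx <- make_ifs_fixture()
  nd <- random_subset_null(fx$table, "expression_specificity", 4, fx$spec,
                           n_iter = 6, k = 5, seed = 7)
  expect_equal(length(nd$mccs), 6)
  expect_equal(nd$mean, mean(nd$mccs))
  expect_equal(nd$sd, sd(nd$mccs))
  nd2 <- random_subset_null(fx$table, "expression_specificity", 4, fx$spec,
                            n_iter = 6, k = 5, seed = 7)
  expect_identical(nd$mccs, nd2$mccs)
  expect_error(random_subset_null(fx$table, "nope", 4, fx$spec, 3),
               "no feature named")
  expect_error(random_subset_null(fx$table, "expression_specificity", 1,
                                  fx$spec, 3), ">= 2")
})

test_that("degenerate full-size subsets give zero spread", {
  fx <- make_ifs_fixture()
  N <- n_features(fx$table)
  nd <- random_subset_null(fx$table, "expression_specificity", N, fx$spec,
                           n_iter = 4, k = 5, seed = 7)
  expect_equal(nd$sd, 0)
})

test_that("sigma_excess reproduces the published inequality margins", {
  null1 <- list(mean = 0.860, sd = 0.015)
  expect_equal(sigma_excess(0.880, null1), 4 / 3, tolerance = 1e-12)
  expect_gte(sigma_excess(0.880, null1), 1.3)
  null2 <- list(mean = 0.847, sd = 0.015)
  expect_equal(sigma_excess(0.876, null2), 29 / 15, tolerance = 1e-12)
  expect_gte(sigma_excess(0.876, null2), 1.8)
  expect_equal(sigma_excess(0.5, list(mean = 0.5, sd = 0.1)), 0)
  expect_error(sigma_excess(0.5, list(mean = 0.4, sd = 0)), "sd = 0")
})

test_that("box-plot summary is consistent with the stored list", {
  nd <- structure(list(mccs = c(0.1, 0.2, 0.3, 0.4, 0.5, 2)),
                  class = "null_distribution")
  s <- null_summary(nd)
  q <- quantile(nd$mccs, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unname(s[c("q1", "median", "q3")]), q)
  expect_equal(unname(s["upper_whisker"]), 0.5)  # 2 is an outlier
  expect_equal(unname(s["lower_whisker"]), 0.1)
})
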