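test_that("discretize splits at mean +/- alpha * population sd", {
  expect_equal(discretize(c(0, 0, 0, 100)), c(0L, 0L, 0L, 1L))
  expect_equal(discretize(c(5, 5, 5)), c(0L, 0L, 0L))
  expect_equal(discretize(c(-1, 1, -1, 1)), c(-0L, 0L, 0L, 0L))
  # asymmetric case with values beyond both thresholds
  v <- c(rep(0, 8), 10, -10)
  st <- discretize(v)
  expect_equal(st[9], 1L)
  expect_equal(st[10], -1L)
  expect_error(discretize(1), "at least 2")
  expect_error(discretization_spec(alpha = 0), "positive")
})

test_that("mutual information matches the joint-table oracle", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(mutual_information(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:3, 1:4), "length mismatch")
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(-1:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    i <- mutual_information(x, y)
    expect_equal(i, mi_oracle(x, y), tolerance = 1e-12)
    expect_gte(i, 0)
    expect_equal(i, mutual_information(y, x), tolerance = 1e-12)
    hx <- entropy_oracle(table(x))
    hy <- entropy_oracle(table(y))
    expect_lte(i, min(hx, hy) + 1e-9)
  }
})

test_that("duplicate features are demoted by redundancy", {
  tab <- duplicate_toy()
  mr <- mrmr_rank(tab)
  expect_equal(mr$feature_names, c("A", "C", "B"))
  mx <- maxrel_rank(tab)
  expect_equal(mx$feature_names, c("A", "B", "C"))
  expect_equal(mr$order[1], mx$order[1])  # criteria coincide at step 1
})

test_that("greedy ranking matches exhaustive step-by-step oracle", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(30:60, 1)
    nfeat <- sample(4:8, 1)
    y <- sample(c("positive", "negative"), n, replace = TRUE,
                prob = c(0.4, 0.6))
    vals <- matrix(rnorm(n * nfeat) +
                     outer(as.numeric(y == "positive"),
                           runif(nfeat, 0, 2)),
                   n, nfeat)
    vals <- abs(vals)
    tab <- make_table(vals, y)
    disc <- apply(tab$values, 2, discretize)
    expect_equal(mrmr_rank(tab)$order,
                 mrmr_oracle(disc, as.integer(y == "positive")))
  }
})

test_that("ranking is a permutation, invariant to column order", {
  res <- generate_table(synthetic_spec(n_pos = 60, n_neg = 90, n_facets = 8,
                                       n_informative = 3, seed = 11))
  tab <- res$table
  mr <- mrmr_rank(tab)
  expect_setequal(mr$order, seq_len(n_features(tab)))
  perm <- sample(n_features(tab))
  tab2 <- select_features(tab, perm)
  mr2 <- mrmr_rank(tab2)
  # map back to original indices; identical ranking up to tie handling
  expect_equal(mr2$feature_names, mr$feature_names)
})

test_that("single-feature and single-class edge cases", {
  tab <- make_table(matrix(c(1, 2, 3, 4), 4, 1),
                    c("positive", "positive", "negative", "negative"))
  expect_equal(mrmr_rank(tab)$order, 1L)
  solo <- make_table(matrix(1:4, 4, 1), rep("positive", 4))
  expect_error(mrmr_rank(solo), "both classes")
})

test_that("planted informative facets lead the maxrel list", {
  res <- generate_table(synthetic_spec(n_pos = 300, n_neg = 450,
                                       n_facets = 20, n_informative = 5,
                                       effect_log2 = 4, dropout_pos = 0.6,
                                       dropout_neg = 0.2, seed = 13))
  mx <- maxrel_rank(res$table)
  expect_gte(sum(mx$order[1:8] %in% res$informative), 4)
})
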