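test_that("generator is deterministic and structurally correct", {
  spec <- synthetic_spec(n_pos = 50, n_neg = 80, n_facets = 12,
                         n_informative = 4, seed = 41)
  a <- generate_table(spec)
  b <- generate_table(spec)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$informative, b$informative)
  expect_equal(n_features(a$table), 14)  # facets + max CPM + specificity
  expect_equal(sum(a$table$labels == "positive"), 50)
  expect_true(all(a$table$values >= 0))
  expect_equal(tail(a$table$feature_names, 2),
               c("max_cpm_all_facets", "expression_specificity"))
  spec_col <- a$table$values[, "expression_specificity"]
  expect_true(all(spec_col >= 0 & spec_col <= 1))
  # max CPM column really is the row maximum over facets
  expect_equal(a$table$values[, "max_cpm_all_facets"],
               apply(a$table$values[, 1:12], 1, max))
})

test_that("informative facets separate the classes in the stated direction", {
  res <- generate_table(synthetic_spec(n_pos = 1000, n_neg = 1000,
                                       effect_log2 = 1, seed = 43))
  tab <- res$table
  pos <- tab$labels == "positive"
  pvals <- vapply(res$informative, function(j) {
    wilcox.test(tab$values[pos, j], tab$values[!pos, j],
                alternative = "less")$p.value
  }, numeric(1))
  expect_lt(max(pvals), 0.01)
})

test_that("higher dropout gives positives higher specificity", {
  res <- generate_table(synthetic_spec(n_pos = 500, n_neg = 500,
                                       effect_log2 = 0, dropout_pos = 0.6,
                                       dropout_neg = 0.2, seed = 44))
  spec_col <- res$table$values[, "expression_specificity"]
  pos <- res$table$labels == "positive"
  expect_gt(mean(spec_col[pos]), mean(spec_col[!pos]))
})

test_that("exchangeable classes carry no signal", {
  res <- generate_table(synthetic_spec(n_pos = 300, n_neg = 300,
                                       effect_log2 = 0, dropout_pos = 0.4,
                                       dropout_neg = 0.4, seed = 45))
  ms <- cross_validate(res$table,
                       classifier_spec("random_forest",
                                       params = list(B = 30), seed = 3),
                       k = 5, seed = 3)
  expect_lt(abs(ms$MCC), 0.2)  # loose desk-scale bound; tight one in acceptance
})

test_that("invalid generator settings are rejected", {
  expect_error(synthetic_spec(n_informative = 80, n_facets = 69), "exceeds")
  expect_error(synthetic_spec(dropout_pos = 1), "dropout")
  expect_error(synthetic_spec(effect_log2 = -1), ">= 0")
})

test_that("table3 fixture fires each designated rule", {
  fx <- table3_fixture()
  expect_equal(length(fx$ruleset), 17)
  expect_equal(fx$ruleset$default_class, "mRNA")
  expect_true(all(vapply(fx$ruleset$rules, function(r) r$outcome,
                         character(1)) == "lncRNA"))
  res <- apply_ruleset(fx$ruleset, fx$table)
  expect_equal(res$rule_index, attr(fx$table, "expected_rule"))
  expect_equal(res$class,
               unname(fx$table$class_names[fx$table$labels]))
  # feature names from the published top-13 list are all present
  expect_true(all(c("Expression specificity", "Intestinal epithelial cell",
                    "Neuronal stem cell", "Max cpm in all facet") %in%
                    fx$table$feature_names))
})
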