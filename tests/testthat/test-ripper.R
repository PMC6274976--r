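test_that("clean 1-D threshold data yields one exact rule", {
  tab <- margin_toy(seed = 1)
  rs <- ripper_train(tab, ripper_params(seed = 11))
  expect_equal(length(rs), 1)
  r <- rs$rules[[1]]
  expect_equal(length(r$conditions), 1)
  expect_equal(r$conditions[[1]]$feature, "x")
  expect_equal(r$conditions[[1]]$relation, "<=")
  expect_equal(r$outcome, "lncRNA")       # positives are the minority
  expect_equal(rs$default_class, "mRNA")
  x <- tab$values[, 1]
  pos <- tab$labels == "positive"
  thr <- r$conditions[[1]]$threshold
  expect_gte(thr, max(x[pos]))            # bracketed by the class gap
  expect_lte(thr, min(x[!pos]))
  pred <- apply_ruleset(rs, tab)
  expect_equal(pred$class == "lncRNA", pos)  # zero training errors
})

test_that("pure-noise labels learn zero conditional rules", {
  set.seed(2)
  vals <- matrix(runif(500 * 10), 500, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  labels <- sample(c(rep("positive", 200), rep("negative", 300)))
  tab <- make_table(vals, labels)
  rs <- ripper_train(tab, ripper_params(seed = 4))
  expect_equal(length(rs), 0)
  expect_equal(rs$default_class, "mRNA")
  expect_equal(apply_ruleset(rs, tab)$class, rep("mRNA", 500))
})

test_that("training is deterministic and rules meet minimum coverage", {
  res <- generate_table(synthetic_spec(n_pos = 150, n_neg = 220,
                                       n_facets = 12, n_informative = 4,
                                       effect_log2 = 3, seed = 17))
  rs1 <- ripper_train(res$table, ripper_params(seed = 5))
  rs2 <- ripper_train(res$table, ripper_params(seed = 5))
  expect_identical(format_ruleset(rs1), format_ruleset(rs2))
  expect_gt(length(rs1), 0)
  for (r in rs1$rules) {
    covered <- apply(res$table$values, 1, function(row) {
      all(vapply(r$conditions, function(cond) {
        if (cond$relation == "<=") row[cond$feature] <= cond$threshold
        else row[cond$feature] >= cond$threshold
      }, logical(1)))
    })
    expect_gte(sum(covered), 2)
  }
})

test_that("rule order matters: permuting rules can change predictions", {
  rs <- ruleset(list(
    rule(list(condition("x", "<=", 5)), "lncRNA"),
    rule(list(condition("x", "<=", 10)), "mRNA")), "mRNA")
  swapped <- ruleset(rev(rs$rules), "mRNA")
  sample <- c(x = 3)
  expect_equal(apply_ruleset(rs, sample)$class, "lncRNA")
  expect_equal(apply_ruleset(swapped, sample)$class, "mRNA")
})

test_that("apply_ruleset is first-match with a working default", {
  empty <- ruleset(list(), "lncRNA")
  expect_equal(apply_ruleset(empty, c(whatever = 1))$class, "lncRNA")
  rs <- ruleset(list(rule(list(condition("a", ">=", 2),
                               condition("b", "<=", 0)), "lncRNA")),
                "mRNA")
  res <- apply_ruleset(rs, rbind(c(a = 3, b = 0), c(a = 3, b = 1)))
  expect_equal(res$class, c("lncRNA", "mRNA"))
  expect_equal(res$rule_index, c(1L, 2L))
  expect_error(apply_ruleset(rs, c(a = 1)), "lacks feature 'b'")
})

test_that("rule text round-trips through format and parse", {
  set.seed(31)
  for (rep in 1:100) {
    n_rules <- sample(0:5, 1)
    feats <- c("Neuronal stem cell", "Mast cell", "x1", "f 2")
    rules <- lapply(seq_len(n_rules), function(i) {
      k <- sample(1:4, 1)
      rule(lapply(seq_len(k), function(j) {
        condition(sample(feats, 1), sample(c("<=", ">="), 1),
                  signif(rexp(1) * 10^sample(-3:3, 1), sample(1:6, 1)))
      }), sample(c("lncRNA", "mRNA"), 1))
    })
    rs <- ruleset(rules, sample(c("lncRNA", "mRNA"), 1))
    txt <- format_ruleset(rs)
    back <- parse_ruleset(txt)
    expect_equal(back, rs)
    expect_identical(format_ruleset(back), txt)
  }
})

test_that("parser accepts unicode relations and rejects malformed input", {
  rs <- parse_ruleset(c("(Mast cell ≤ 0.151) and (x ≥ 2) => lncRNA",
                        "Otherwise => mRNA"))
  expect_equal(rs$rules[[1]]$conditions[[1]]$relation, "<=")
  expect_equal(rs$rules[[1]]$conditions[[2]]$relation, ">=")
  expect_error(parse_ruleset("(x <= 1) => lncRNA"), "Otherwise")
  expect_error(parse_ruleset(c("(x = 1) => lncRNA", "Otherwise => mRNA")),
               "malformed")
  expect_error(parse_ruleset(c("x <= => lncRNA", "Otherwise => mRNA")),
               "malformed")
})

test_that("write_ruleset emits a parseable file", {
  rs <- ruleset(list(rule(list(condition("Hepatocyte", "<=", 0)), "lncRNA")),
                "mRNA")
  f <- withr::local_tempfile(fileext = ".txt")
  write_ruleset(rs, f)
  expect_equal(parse_ruleset(f), rs)
})

test_that("single-class and empty tables are rejected", {
  solo <- make_table(matrix(1:4, 4, 1), rep("positive", 4))
  expect_error(ripper_train(solo), "both classes")
})
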