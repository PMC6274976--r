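#' RIPPER hyperparameters
#'
#' Defaults follow the canonical RIPPER/JRip settings: a third of the data
#' held out for rule pruning, a minimum rule coverage of 2 samples, two
#' optimization passes, and a 64-bit description-length slack for the MDL
#' stopping criterion.
#'
#' @param prune_fraction Fraction of the data held out to prune each rule,
#'   in (0, 1).
#' @param min_covered Minimum number of training samples a kept rule must
#'   cover (positive integer).
#' @param optimization_passes Number of optimization sweeps in which each
#'   rule competes against a freshly grown replacement and a revision.
#' @param dl_slack_bits Stop adding rules once the ruleset description
#'   length exceeds the minimum seen plus this many bits.
#' @param seed Integer seed for the grow/prune splits.
#' @return A list of class `ripper_params`.
#' @export
ripper_params <- function(prune_fraction = 1 / 3, min_covered = 2L,
                          optimization_passes = 2L, dl_slack_bits = 64,
                          seed = 1L) {
  if (prune_fraction <= 0 || prune_fraction >= 1) {
    stopf("ripper_params: prune_fraction must be in (0, 1)")
  }
  if (min_covered < 1) stopf("ripper_params: min_covered must be >= 1")
  if (optimization_passes < 0) stopf("ripper_params: negative passes")
  if (dl_slack_bits <= 0) stopf("ripper_params: dl_slack_bits must be > 0")
  structure(list(prune_fraction = prune_fraction,
                 min_covered = as.integer(min_covered),
                 optimization_passes = as.integer(optimization_passes),
                 dl_slack_bits = dl_slack_bits, seed = as.integer(seed)),
            class = "ripper_params")
}

# ---- internal representation -------------------------------------------
# During learning a condition is list(j = column index, rel = "<="|">=",
# thr = numeric); rules are lists of such conditions. Conversion to the
# public ruleset happens at the end.

cover_conds <- function(conds, X) {
  out <- rep(TRUE, nrow(X))
  for (cond in conds) {
    out <- out & if (cond$rel == "<=") X[, cond$j] <= cond$thr
                 else X[, cond$j] >= cond$thr
  }
  out
}

# Greedy FOIL-gain growth. Candidate thresholds are midpoints between
# adjacent distinct observed values in the grow set, so an error-free split
# lands in the middle of the empirical margin. Ties break toward the
# smaller column index, then "<=" before ">=".
grow_rule <- function(X, y, conds = list(), max_len = 100L) {
  covered <- cover_conds(conds, X)
  repeat {
    P <- sum(y[covered])
    N <- sum(covered) - P
    if (N == 0 || P == 0 || length(conds) >= max_len) break
    base <- log2(P / (P + N))
    best_gain <- 1e-10
    best <- NULL
    for (j in seq_len(ncol(X))) {
      v <- X[covered, j]
      yy <- y[covered]
      o <- order(v)
      v <- v[o]; yy <- yy[o]
      ch <- which(diff(v) > 0)
      if (length(ch) == 0) next
      cp <- cumsum(yy)
      thr <- (v[ch] + v[ch + 1]) / 2
      p_le <- cp[ch]; n_le <- ch - p_le
      g_le <- ifelse(p_le > 0,
                     p_le * (log2(p_le / (p_le + n_le)) - base), -Inf)
      p_ge <- P - p_le; n_ge <- N - n_le
      g_ge <- ifelse(p_ge > 0,
                     p_ge * (log2(p_ge / (p_ge + n_ge)) - base), -Inf)
      i_le <- which.max(g_le)
      if (g_le[i_le] > best_gain) {
        best_gain <- g_le[i_le]
        best <- list(j = j, rel = "<=", thr = thr[i_le])
      }
      i_ge <- which.max(g_ge)
      if (g_ge[i_ge] > best_gain) {
        best_gain <- g_ge[i_ge]
        best <- list(j = j, rel = ">=", thr = thr[i_ge])
      }
    }
    if (is.null(best)) break
    conds <- c(conds, list(best))
    covered <- covered & if (best$rel == "<=") X[, best$j] <= best$thr
                         else X[, best$j] >= best$thr
  }
  conds
}

# Delete the final condition sequence maximizing (p - n) / (p + n) on the
# prune set (worth 0 when the prefix covers nothing there). Ties prefer the
# shorter prefix, i.e. more aggressive pruning.
prune_rule <- function(conds, Xp, yp) {
  if (length(conds) <= 1 || nrow(Xp) == 0) return(conds)
  worth <- numeric(length(conds))
  covered <- rep(TRUE, nrow(Xp))
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    covered <- covered & if (cond$rel == "<=") Xp[, cond$j] <= cond$thr
                         else Xp[, cond$j] >= cond$thr
    p <- sum(yp[covered]); n <- sum(covered) - p
    worth[i] <- if (p + n == 0) 0 else (p - n) / (p + n)
  }
  conds[seq_len(which.max(worth))]
}

stratified_split <- function(y, grow_fraction, seed) {
  with_seed(seed, {
    grow <- logical(length(y))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      if (length(idx) == 0) next
      n_grow <- ceiling(grow_fraction * length(idx))
      grow[idx[sample.int(length(idx))][seq_len(n_grow)]] <- TRUE
    }
    grow
  })
}

# ---- description length -------------------------------------------------
# MDL accounting in the spirit of Cohen (1995): a ruleset costs theory bits
# (encode each rule's conditions) plus exception bits (encode which covered
# samples are false positives and which uncovered samples are false
# negatives, via binomial codes). Only differences in DL matter, so the
# accounting is deliberately simple; it gates stopping and rule deletion,
# not rule semantics.

log2choose <- function(n, k) lchoose(n, k) / log(2)

ripper_theory_dl <- function(rules, n_features, n_vals) {
  if (length(rules) == 0) return(0)
  sum(vapply(rules, function(conds) {
    k <- length(conds)
    bits <- log2(k + 1)
    for (cond in conds) {
      bits <- bits + log2(n_features) + 1 +
        log2(max(2, n_vals[cond$j]))
    }
    0.5 * bits  # redundancy discount, as in the canonical implementation
  }, numeric(1)))
}

ripper_exception_dl <- function(rules, X, y) {
  n <- nrow(X)
  covered <- rep(FALSE, n)
  for (conds in rules) covered <- covered | cover_conds(conds, X)
  cc <- sum(covered)
  u <- n - cc
  fp <- sum(covered & !y)
  fn <- sum(!covered & y)
  log2choose(cc, fp) + log2choose(u, fn) + log2(cc + 1) + log2(u + 1)
}

ripper_total_dl <- function(rules, X, y, n_vals) {
  ripper_theory_dl(rules, ncol(X), n_vals) + ripper_exception_dl(rules, X, y)
}

rule_precision <- function(conds, X, y) {
  covered <- cover_conds(conds, X)
  tot <- sum(covered)
  if (tot == 0) return(c(precision = NA_real_, covered = 0))
  c(precision = sum(y[covered]) / tot, covered = tot)
}

# ---- main learner -------------------------------------------------------

#' Train a RIPPER rule list
#'
#' Repeated incremental pruning to produce error reduction, for binary
#' classification over numeric features. Rules are learned for the minority
#' class (ties go to the positive class) and the default class is the
#' majority. Each rule is grown greedily by FOIL information gain on a grow
#' partition, pruned on a held-out prune partition, and admitted only while
#' the rule's held-out error stays below one half and the ruleset
#' description length stays within `dl_slack_bits` of the best seen.
#' Optimization passes then let every rule compete against a freshly grown
#' replacement and a greedy revision (keeping the description-length
#' minimizer), and rules whose removal lowers the total description length
#' are dropped.
#'
#' @param table A [feature_table()] with both classes present.
#' @param params A [ripper_params()].
#' @return A [ruleset()] whose rule outcomes use the table's display class
#'   names (e.g. `lncRNA` rules with an `mRNA` default), with attributes
#'   `target` (display name of the rule class) and `params`.
#' @export
ripper_train <- function(table, params = ripper_params()) {
  if (n_samples(table) == 0) stopf("ripper_train: empty table")
  if (length(unique(table$labels)) < 2) {
    stopf("ripper_train: both classes must be present")
  }
  X <- table$values
  n_pos <- sum(table$labels == "positive")
  n_neg <- n_samples(table) - n_pos
  target <- if (n_pos <= n_neg) "positive" else "negative"
  y <- table$labels == target
  n_vals <- apply(X, 2, function(col) length(unique(col)))
  grow_fraction <- 1 - params$prune_fraction

  rules <- list()
  remaining <- rep(TRUE, nrow(X))
  dl_min <- ripper_total_dl(rules, X, y, n_vals)
  iter <- 0L
  while (sum(y & remaining) > 0) {
    iter <- iter + 1L
    idx <- which(remaining)
    grow_mask <- stratified_split(y[idx], grow_fraction,
                                  mix_seed(params$seed, iter))
    gi <- idx[grow_mask]
    pi <- idx[!grow_mask]
    conds <- grow_rule(X[gi, , drop = FALSE], y[gi])
    if (length(conds) == 0) break
    conds <- prune_rule(conds, X[pi, , drop = FALSE], y[pi])
    # held-out error check: the rule must be majority-correct where it can
    # be measured (prune set if it covers anything there, else grow set)
    pr <- rule_precision(conds, X[pi, , drop = FALSE], y[pi])
    if (is.na(pr["precision"])) {
      pr <- rule_precision(conds, X[gi, , drop = FALSE], y[gi])
    }
    if (is.na(pr["precision"]) || pr["precision"] <= 0.5) break
    cover_rem <- cover_conds(conds, X[idx, , drop = FALSE])
    if (sum(cover_rem) < params$min_covered) break
    cand <- c(rules, list(conds))
    dl <- ripper_total_dl(cand, X, y, n_vals)
    if (dl > dl_min + params$dl_slack_bits) break
    dl_min <- min(dl_min, dl)
    rules <- cand
    remaining[idx[cover_rem]] <- FALSE
  }

  # optimization passes: replacement vs revision vs original, by total DL
  if (length(rules) > 0 && params$optimization_passes > 0) {
    for (pass in seq_len(params$optimization_passes)) {
      for (r in seq_along(rules)) {
        others <- rules[-r]
        covered_others <- rep(FALSE, nrow(X))
        for (conds in others) {
          covered_others <- covered_others | cover_conds(conds, X)
        }
        idx <- which(!covered_others)
        if (sum(y[idx]) == 0 || sum(!y[idx]) == 0) next
        grow_mask <- stratified_split(y[idx], grow_fraction,
                                      mix_seed(params$seed,
                                               1000L + pass * 100L + r))
        gi <- idx[grow_mask]
        pi <- idx[!grow_mask]
        cands <- list(rules[[r]])
        repl <- grow_rule(X[gi, , drop = FALSE], y[gi])
        if (length(repl) > 0) {
          cands <- c(cands, list(prune_rule(repl, X[pi, , drop = FALSE],
                                            y[pi])))
        }
        revn <- grow_rule(X[gi, , drop = FALSE], y[gi],
                          conds = rules[[r]])
        if (length(revn) > 0) {
          cands <- c(cands, list(prune_rule(revn, X[pi, , drop = FALSE],
                                            y[pi])))
        }
        dls <- vapply(cands, function(v) {
          trial <- rules
          trial[[r]] <- v
          ripper_total_dl(trial, X, y, n_vals)
        }, numeric(1))
        rules[[r]] <- cands[[which.min(dls)]]
      }
    }
  }

  # delete rules whose removal lowers the total description length
  repeat {
    if (length(rules) == 0) break
    current <- ripper_total_dl(rules, X, y, n_vals)
    dls <- vapply(seq_along(rules), function(r) {
      ripper_total_dl(rules[-r], X, y, n_vals)
    }, numeric(1))
    if (min(dls) < current - 1e-9) {
      rules <- rules[-which.min(dls)]
    } else {
      break
    }
  }

  target_name <- unname(table$class_names[[target]])
  default_name <- unname(
    table$class_names[[setdiff(c("positive", "negative"), target)]])
  public <- lapply(rules, function(conds) {
    rule(lapply(conds, function(cond) {
      condition(table$feature_names[cond$j], cond$rel, cond$thr)
    }), target_name)
  })
  rs <- ruleset(public, default_name)
  attr(rs, "target") <- target_name
  attr(rs, "params") <- params
  rs
}
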