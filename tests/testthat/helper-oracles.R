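# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# Mutual information via an explicit joint table (bits).
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  as.numeric(s)
}

# Plug-in Shannon entropy in bits.
entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Literal evaluation of the four performance formulas.
metrics_oracle <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / total
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(SN = sn, SP = sp, ACC = acc, MCC = mcc)
}

# Step-by-step exhaustive mRMR (MID) oracle on a discretized matrix.
mrmr_oracle <- function(disc, y) {
  nfeat <- ncol(disc)
  rel <- vapply(seq_len(nfeat), function(j) mi_oracle(disc[, j], y),
                numeric(1))
  selected <- integer(0)
  remaining <- seq_len(nfeat)
  while (length(remaining) > 0) {
    sc <- vapply(remaining, function(j) {
      if (length(selected) == 0) return(rel[j])
      red <- mean(vapply(selected, function(s) mi_oracle(disc[, j], disc[, s]),
                         numeric(1)))
      rel[j] - red
    }, numeric(1))
    best <- remaining[which.max(sc)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# Small labeled table with named features.
make_table <- function(values, labels, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  feature_table(ids %||% sprintf("s%03d", seq_len(nrow(values))), labels,
                values)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-D margin toy: positives (minority) uniform below the gap, negatives
# above it. Clean and linearly separable with a margin.
margin_toy <- function(n_pos = 80, n_neg = 120, gap = c(0.45, 0.55),
                       seed = 1) {
  set.seed(seed)
  x <- c(runif(n_pos, 0, gap[1]), runif(n_neg, gap[2], 1))
  make_table(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
             c(rep("positive", n_pos), rep("negative", n_neg)))
}

# Duplicate-feature toy for the ranking oracle: A is a noisy class signal,
# B its exact duplicate, C independent noise. The 10% label noise keeps the
# duplicate's redundancy penalty strictly negative (a noiseless copy would
# score exactly zero at step two and tie with noise).
duplicate_toy <- function(n = 200, seed = 3) {
  set.seed(seed)
  cls <- c(rep(1, round(0.3 * n)), rep(0, n - round(0.3 * n)))
  flip <- runif(n) < 0.1
  a <- 100 * ifelse(flip, 1 - cls, cls)
  c_noise <- abs(rnorm(n))
  make_table(cbind(A = a, B = a, C = c_noise),
             ifelse(cls == 1, "positive", "negative"))
}
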