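#' Classifier specification
#'
#' Names one of the five supported algorithms together with its parameters
#' and a seed for any stochastic component.
#'
#' Supported algorithms and parameters:
#' \describe{
#'   \item{`random_forest`}{`B` trees (default 100) on bootstrap resamples;
#'     at every split a fresh random subset of `m` features is tried
#'     (default `floor(log2(M) + 1)` of `M` features); prediction by hard
#'     majority vote (vote ties go to the negative class).}
#'   \item{`ripper`}{ordered-rule learner; parameters via [ripper_params()].}
#'   \item{`one_nn`}{single Euclidean nearest neighbour (distance ties go to
#'     the earlier training row).}
#'   \item{`linear_svm`}{L2-regularized squared-hinge linear SVM on
#'     standardized features, `cost = 1`, fitted with BFGS.}
#'   \item{`logistic`}{`stats::glm` binomial fit; probability 0.5 threshold.}
#' }
#'
#' @param algorithm One of `"random_forest"`, `"ripper"`, `"one_nn"`,
#'   `"linear_svm"`, `"logistic"`.
#' @param params Named list of algorithm parameters (see Details).
#' @param seed Integer seed consumed by stochastic algorithms.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, c("random_forest", "ripper", "one_nn",
                                      "linear_svm", "logistic"))
  if (!is.null(params$B) && params$B < 1) stopf("classifier_spec: B must be >= 1")
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier on a feature table
#'
#' @param table A [feature_table()] with both classes present.
#' @param spec A [classifier_spec()].
#' @return An object of class `lnc_model` with a [predict.lnc_model()]
#'   method returning `"positive"`/`"negative"` labels.
#' @export
train_classifier <- function(table, spec) {
  if (!inherits(spec, "classifier_spec")) stopf("spec must be a classifier_spec")
  if (length(unique(table$labels)) < 2) {
    stopf("train_classifier: both classes must be present")
  }
  fit <- switch(spec$algorithm,
    random_forest = fit_random_forest(table, spec),
    one_nn = fit_one_nn(table, spec),
    linear_svm = fit_linear_svm(table, spec),
    logistic = fit_logistic(table, spec),
    ripper = fit_ripper(table, spec)
  )
  structure(list(algorithm = spec$algorithm, fit = fit, spec = spec,
                 feature_names = table$feature_names,
                 class_names = table$class_names),
            class = "lnc_model")
}

#' @export
print.lnc_model <- function(x, ...) {
  cat(sprintf("lnc_model: %s on %d features\n", x$algorithm,
              length(x$feature_names)))
  invisible(x)
}

#' Predict classes for new samples
#'
#' @param object A trained `lnc_model`.
#' @param newdata A [feature_table()] or numeric matrix whose columns match
#'   the training features.
#' @param ... Unused.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
predict.lnc_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != length(object$feature_names)) {
    stopf("predict: %d columns supplied, %d expected", ncol(X),
          length(object$feature_names))
  }
  object$fit$predict(X)
}

as_binary <- function(labels) ifelse(labels == "positive", 1L, 0L)

fit_random_forest <- function(table, spec) {
  M <- n_features(table)
  B <- as.integer(spec$params$B %||% 100L)
  m <- as.integer(spec$params$m %||% max(1L, floor(log2(M) + 1)))
  m <- min(max(1L, m), M)
  min_node <- as.integer(spec$params$min_node %||% 1L)
  max_depth <- as.integer(spec$params$max_depth %||% 0L)
  forest <- with_seed(spec$seed,
    .rf_fit_cpp(table$values, as_binary(table$labels), B, m, min_node,
                max_depth, TRUE))
  list(forest = forest, predict = function(X) {
    ifelse(.rf_vote_cpp(forest, X) > 0.5, "positive", "negative")
  })
}

fit_one_nn <- function(table, spec) {
  train_x <- table$values
  train_y <- table$labels
  sq <- rowSums(train_x^2)
  list(predict = function(X) {
    # squared Euclidean distances, blockwise to cap memory
    n <- nrow(X)
    out <- character(n)
    block <- 512L
    for (start in seq(1L, n, by = block)) {
      idx <- start:min(start + block - 1L, n)
      cross <- X[idx, , drop = FALSE] %*% t(train_x)
      d <- outer(rowSums(X[idx, , drop = FALSE]^2), sq, "+") - 2 * cross
      out[idx] <- train_y[max.col(-d, ties.method = "first")]
    }
    out
  })
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

fit_linear_svm <- function(table, spec) {
  cost <- spec$params$cost %||% 1
  std <- standardize_fit(table$values)
  Z <- scale(table$values, std$mu, std$sd)
  y <- ifelse(table$labels == "positive", 1, -1)
  n <- nrow(Z)
  p <- ncol(Z)
  obj <- function(w) {
    f <- drop(Z %*% w[1:p]) + w[p + 1]
    xi <- pmax(0, 1 - y * f)
    0.5 * sum(w[1:p]^2) + cost * sum(xi^2) / n
  }
  grad <- function(w) {
    f <- drop(Z %*% w[1:p]) + w[p + 1]
    xi <- pmax(0, 1 - y * f)
    gw <- w[1:p] - (2 * cost / n) * drop(t(Z) %*% (xi * y))
    gb <- -(2 * cost / n) * sum(xi * y)
    c(gw, gb)
  }
  w0 <- numeric(p + 1)
  opt <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  w <- opt$par
  list(predict = function(X) {
    Z2 <- scale(X, std$mu, std$sd)
    f <- drop(Z2 %*% w[1:p]) + w[p + 1]
    ifelse(f > 0, "positive", "negative")
  })
}

fit_logistic <- function(table, spec) {
  df <- as.data.frame(table$values)
  colnames(df) <- paste0("x", seq_len(ncol(df)))
  df$.y <- as_binary(table$labels)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  list(predict = function(X) {
    nd <- as.data.frame(X)
    colnames(nd) <- paste0("x", seq_len(ncol(nd)))
    pr <- suppressWarnings(
      stats::predict(fit, newdata = nd, type = "response"))
    ifelse(pr > 0.5, "positive", "negative")
  })
}

fit_ripper <- function(table, spec) {
  params <- spec$params$ripper %||% ripper_params(seed = spec$seed)
  params$seed <- spec$seed
  rs <- ripper_train(table, params)
  # ruleset outcomes use display class names; map back for prediction
  inv <- stats::setNames(names(table$class_names),
                         unname(table$class_names))
  fn <- table$feature_names
  list(ruleset = rs, predict = function(X) {
    colnames(X) <- fn
    res <- apply_ruleset(rs, X)
    unname(inv[res$class])
  })
}
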