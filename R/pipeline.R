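#' Pipeline configuration
#'
#' Collects every knob of the full analysis: input table, output directory,
#' classifiers to run, fold count, master seed, discretization and RIPPER
#' settings, significance-test settings, and reporting thresholds.
#'
#' @param input Path to a labeled feature table (TSV/CSV).
#' @param out_dir Output directory (created if missing).
#' @param classifiers Character subset of `random_forest`, `ripper`,
#'   `one_nn`, `linear_svm`, `logistic`.
#' @param folds Cross-validation fold count (default 10).
#' @param seed Integer master seed.
#' @param alpha Discretization multiplier for mRMR.
#' @param scheme mRMR scheme, `"MID"` or `"MIQ"`.
#' @param rf_params Named list of random-forest parameters (`B`, `m`, ...).
#' @param ripper RIPPER parameters ([ripper_params()]).
#' @param signif List with `anchor` (feature name; `NULL` picks the first
#'   feature whose name contains "specificity"), `subset_size` (default 13)
#'   and `n_iter` (default 1000).
#' @param thresholds MCC thresholds reported via [first_crossing()].
#' @param stride Evaluate every `stride`-th subset size (default 1 = all).
#' @param max_size Largest IFS subset size (default: all features).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            classifiers = c("random_forest", "ripper",
                                            "one_nn", "linear_svm",
                                            "logistic"),
                            folds = 10L, seed = 1L, alpha = 1,
                            scheme = "MID", rf_params = list(),
                            ripper = ripper_params(seed = seed),
                            signif = list(anchor = NULL, subset_size = 13L,
                                          n_iter = 1000L),
                            thresholds = numeric(0), stride = 1L,
                            max_size = NULL) {
  if (length(classifiers) < 1) stopf("pipeline_config: need >= 1 classifier")
  classifiers <- vapply(classifiers, function(a) {
    match.arg(a, c("random_forest", "ripper", "one_nn", "linear_svm",
                   "logistic"))
  }, character(1))
  structure(list(input = input, out_dir = out_dir,
                 classifiers = unname(classifiers),
                 folds = as.integer(folds),
                 seed = as.integer(seed), alpha = alpha, scheme = scheme,
                 rf_params = rf_params, ripper = ripper, signif = signif,
                 thresholds = thresholds, stride = as.integer(stride),
                 max_size = max_size),
            class = "pipeline_config")
}

classifier_from_config <- function(config, algorithm) {
  params <- switch(algorithm,
    random_forest = config$rf_params,
    ripper = list(ripper = config$ripper),
    list())
  classifier_spec(algorithm, params = params, seed = config$seed)
}

#' Run the full analysis pipeline
#'
#' Reads the input table, ranks features (mRMR and MaxRel), runs incremental
#' feature selection per requested classifier, extracts each classifier's
#' optimal point into a summary table (algorithm, number of features, SN,
#' SP, ACC, MCC), trains and writes the rule list for the RIPPER branch on
#' its optimal subset, runs the randomized-subset significance test against
#' the anchor feature, and writes a machine-readable JSON manifest. All
#' outputs are deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out <- function(...) file.path(config$out_dir, ...)
  stage_log <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stage_log[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    res
  }

  table <- stage("read", read_feature_table(config$input))
  dspec <- discretization_spec(alpha = config$alpha)
  ranking <- stage("mrmr_rank", mrmr_rank(table, dspec, config$scheme))
  maxrel <- stage("maxrel_rank", maxrel_rank(table, dspec))
  write_ranking(ranking, out("ranked_mrmr.tsv"))
  write_ranking(maxrel, out("ranked_maxrel.tsv"))

  N <- n_features(table)
  max_size <- config$max_size %||% N
  sizes <- seq(1L, max_size, by = config$stride)
  if (sizes[length(sizes)] != max_size) sizes <- c(sizes, max_size)

  summary_rows <- list()
  ifs_files <- character(0)
  curves <- list()
  for (alg in config$classifiers) {
    spec <- classifier_from_config(config, alg)
    curve <- stage(paste0("ifs_", alg),
                   run_ifs(table, ranking, spec, k = config$folds,
                           seed = config$seed, sizes = sizes))
    f <- out(paste0("ifs_", alg, ".tsv"))
    write_ifs_curve(curve, f)
    ifs_files <- c(ifs_files, f)
    curves[[alg]] <- curve
    opt <- optimal_point(curve)
    summary_rows[[alg]] <- data.frame(
      algorithm = alg, n_features = opt$size, SN = opt$metrics$SN,
      SP = opt$metrics$SP, ACC = opt$metrics$ACC, MCC = opt$metrics$MCC)
  }
  summary_df <- do.call(rbind, summary_rows)
  utils::write.table(summary_df, out("optimal_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  crossings <- lapply(config$thresholds, function(thr) {
    lapply(curves, function(curve) first_crossing(curve, thr))
  })
  names(crossings) <- as.character(config$thresholds)

  ruleset_file <- NULL
  if ("ripper" %in% config$classifiers) {
    opt_size <- summary_rows[["ripper"]]$n_features
    sub <- select_features(table, ranking$order[seq_len(opt_size)])
    rp <- config$ripper
    rp$seed <- config$seed
    rs <- stage("ripper_rules", ripper_train(sub, rp))
    ruleset_file <- out("ruleset.txt")
    write_ruleset(rs, ruleset_file)
  }

  sig <- config$signif
  anchor <- sig$anchor %||% {
    hit <- which(is_specificity_name(table$feature_names))
    if (length(hit) == 0) NULL else table$feature_names[hit[1]]
  }
  signif_summary <- NULL
  if (!is.null(anchor)) {
    sig_spec <- classifier_from_config(
      config, if ("random_forest" %in% config$classifiers) "random_forest"
              else config$classifiers[1])
    null <- stage("significance",
                  random_subset_null(table, anchor,
                                     sig$subset_size %||% 13L, sig_spec,
                                     n_iter = sig$n_iter %||% 1000L,
                                     k = config$folds, seed = config$seed))
    utils::write.table(data.frame(iteration = seq_along(null$mccs),
                                  MCC = null$mccs),
                       out("null_mccs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    observed <- if (!is.null(curves[[sig_spec$algorithm]])) {
      curve <- curves[[sig_spec$algorithm]]
      idx <- which(curve$i == (sig$subset_size %||% 13L))
      if (length(idx) == 1) curve$MCC[idx] else NA_real_
    } else NA_real_
    signif_summary <- list(
      anchor = anchor, subset_size = sig$subset_size %||% 13L,
      n_iter = length(null$mccs), mean = null$mean, sd = null$sd,
      observed_mcc = observed,
      sigma_excess = if (is.finite(observed) && null$sd > 0) {
        sigma_excess(observed, null)
      } else NA_real_,
      boxplot = as.list(null_summary(null)))
    writeLines(jsonlite::toJSON(signif_summary, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE, na = "null"),
               out("significance_summary.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lncpattern")),
    seed = config$seed,
    config = config[setdiff(names(config), "ripper")],
    ripper_params = unclass(config$ripper),
    outputs = list(
      ranked_mrmr = out("ranked_mrmr.tsv"),
      ranked_maxrel = out("ranked_maxrel.tsv"),
      ifs = as.list(stats::setNames(ifs_files,
                                    config$classifiers)),
      optimal_summary = out("optimal_summary.tsv"),
      ruleset = ruleset_file,
      null_mccs = if (!is.null(signif_summary)) out("null_mccs.tsv") else NULL,
      significance_summary = if (!is.null(signif_summary)) {
        out("significance_summary.json")
      } else NULL),
    first_crossings = crossings,
    significance = signif_summary,
    stage_seconds = stage_log,
    wall_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null", null = "null"),
             out("manifest.json"))
  invisible(manifest)
}
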