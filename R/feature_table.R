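#' Labeled gene-by-feature expression table
#'
#' The unit of data every stage of the workflow consumes: one row per
#' transcript, a binary class label (positive = lncRNA, negative = mRNA), and
#' numeric expression-derived features (per-facet maximum CPM values, an
#' overall maximum CPM, and an expression-specificity score).
#'
#' @param ids Character vector of unique transcript identifiers.
#' @param labels Character vector in `c("positive", "negative")`, one per row.
#' @param values Numeric matrix, `length(ids)` rows and one column per feature.
#' @param feature_names Character vector of unique feature names; defaults to
#'   the column names of `values`.
#' @param class_names Named character vector of length 2 giving the display
#'   names of the positive and negative class (defaults `lncRNA` / `mRNA`).
#'
#' @return An object of class `feature_table` with fields `ids`, `labels`,
#'   `values`, `feature_names`, `class_names`.
#' @examples
#' tab <- feature_table(
#'   ids = c("t1", "t2"), labels = c("positive", "negative"),
#'   values = matrix(c(1, 2, 0, 5), 2, dimnames = list(NULL, c("a", "b")))
#' )
#' n_features(tab)
#' @export
feature_table <- function(ids, labels, values,
                          feature_names = colnames(values),
                          class_names = c(positive = "lncRNA",
                                          negative = "mRNA")) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- if (ncol(values) > 0) paste0("f", seq_len(ncol(values)))
    else character(0)
  }
  colnames(values) <- feature_names
  obj <- structure(
    list(ids = as.character(ids), labels = as.character(labels),
         values = values, feature_names = as.character(feature_names),
         class_names = class_names),
    class = "feature_table"
  )
  validate_feature_table(obj)
  obj
}

validate_feature_table <- function(x) {
  n <- length(x$ids)
  if (length(x$labels) != n || nrow(x$values) != n) {
    stopf("feature_table: %d ids, %d labels, %d value rows must all agree",
          n, length(x$labels), nrow(x$values))
  }
  if (anyDuplicated(x$ids)) {
    stopf("feature_table: duplicate ids: %s",
          paste(unique(x$ids[duplicated(x$ids)]), collapse = ", "))
  }
  if (!all(x$labels %in% c("positive", "negative"))) {
    stopf("feature_table: labels must be 'positive' or 'negative'")
  }
  if (ncol(x$values) != length(x$feature_names)) {
    stopf("feature_table: %d value columns vs %d feature names",
          ncol(x$values), length(x$feature_names))
  }
  if (anyDuplicated(x$feature_names)) {
    stopf("feature_table: duplicate feature names: %s",
          paste(unique(x$feature_names[duplicated(x$feature_names)]),
                collapse = ", "))
  }
  if (n > 0 && ncol(x$values) > 0) {
    bad <- which(!is.finite(x$values), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stopf("feature_table: non-finite value at row %d (id '%s'), column '%s'",
            bad[1, 1], x$ids[bad[1, 1]], x$feature_names[bad[1, 2]])
    }
    # Expression columns must be non-negative; the specificity score lives in
    # [0, 1]. A column is treated as specificity when its name says so.
    spec_col <- is_specificity_name(x$feature_names)
    if (any(!spec_col)) {
      expr <- x$values[, !spec_col, drop = FALSE]
      neg <- which(expr < 0, arr.ind = TRUE)
      if (nrow(neg) > 0) {
        nm <- x$feature_names[!spec_col][neg[1, 2]]
        stopf("feature_table: negative expression at row %d (id '%s'), column '%s'",
              neg[1, 1], x$ids[neg[1, 1]], nm)
      }
    }
    if (any(spec_col)) {
      sp <- x$values[, spec_col, drop = FALSE]
      out <- which(sp < 0 | sp > 1, arr.ind = TRUE)
      if (nrow(out) > 0) {
        nm <- x$feature_names[spec_col][out[1, 2]]
        stopf("feature_table: specificity outside [0,1] at row %d, column '%s'",
              out[1, 1], nm)
      }
    }
  }
  invisible(x)
}

is_specificity_name <- function(nm) {
  grepl("specificity", nm, ignore.case = TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples (%d %s / %d %s), %d features\n",
    length(x$ids), sum(x$labels == "positive"), x$class_names[["positive"]],
    sum(x$labels == "negative"), x$class_names[["negative"]],
    length(x$feature_names)))
  invisible(x)
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
n_samples <- function(x) length(x$ids)

#' @rdname feature_table
#' @export
n_features <- function(x) length(x$feature_names)

guess_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labeled feature table from TSV/CSV
#'
#' Expects a header row and columns `id`, `class`, then one column per
#' feature. Class labels `lncRNA`/`mRNA` (case-insensitive) map to the
#' positive/negative convention; anything else is rejected. The delimiter is
#' auto-detected from the extension (`.csv` comma, otherwise tab) unless
#' given.
#'
#' @param path File to read.
#' @param delimiter Field separator; `NULL` (default) auto-detects.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stopf("read_feature_table: no such file: %s", path)
  delimiter <- guess_delimiter(path, delimiter)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stopf("read_feature_table: need at least id and class columns")
  ids <- df[[1]]
  raw_labels <- df[[2]]
  lab_low <- tolower(raw_labels)
  known <- c(lncrna = "positive", mrna = "negative")
  if (!all(lab_low %in% names(known))) {
    bad <- which(!(lab_low %in% names(known)))[1]
    stopf("read_feature_table: unknown class label '%s' at data row %d (expected lncRNA or mRNA)",
          raw_labels[bad], bad)
  }
  labels <- unname(known[lab_low])
  feature_names <- colnames(df)[-(1:2)]
  nfeat <- length(feature_names)
  if (nfeat > 0) {
    vals <- suppressWarnings(
      vapply(df[-(1:2)], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(NULL, feature_names))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stopf("read_feature_table: non-numeric cell '%s' at data row %d, column '%s'",
            df[bad[1, 1], bad[1, 2] + 2L], bad[1, 1], feature_names[bad[1, 2]])
    }
  } else {
    vals <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  }
  feature_table(ids, labels, vals, feature_names)
}

#' Write a feature table to TSV/CSV
#'
#' Values are rendered with enough digits to round-trip exactly through
#' [read_feature_table()]. Class labels are written using the table's display
#' names (default `lncRNA`/`mRNA`).
#'
#' @param table A [feature_table()].
#' @param path Output file.
#' @param delimiter Field separator; `NULL` auto-detects from extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delimiter = NULL) {
  validate_feature_table(table)
  delimiter <- guess_delimiter(path, delimiter)
  labs <- unname(table$class_names[table$labels])
  header <- paste(c("id", "class", table$feature_names), collapse = delimiter)
  if (n_features(table) > 0) {
    chr <- apply(table$values, 2, num_to_string)
    chr <- matrix(chr, nrow = n_samples(table))
    rows <- cbind(table$ids, labs, chr)
  } else {
    rows <- cbind(table$ids, labs)
  }
  lines <- c(header, apply(rows, 1, paste, collapse = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Column-slice a feature table
#'
#' Keeps the requested features, in the requested order, with all samples and
#' labels untouched. This is the subset operation behind incremental feature
#' selection, where the first `i` features of a ranked list form the working
#' table.
#'
#' @param table A [feature_table()].
#' @param subset Integer vector of unique, in-range feature indices (1-based).
#' @return A [feature_table()] with `length(subset)` feature columns.
#' @export
select_features <- function(table, subset) {
  subset <- as.integer(subset)
  if (length(subset) > 0) {
    if (anyDuplicated(subset)) stopf("select_features: duplicate indices")
    if (any(subset < 1 | subset > n_features(table))) {
      stopf("select_features: index out of range 1..%d", n_features(table))
    }
  }
  feature_table(table$ids, table$labels,
                table$values[, subset, drop = FALSE],
                table$feature_names[subset], table$class_names)
}
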