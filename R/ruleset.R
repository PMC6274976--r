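#' Ordered threshold-rule model
#'
#' A ruleset is an ordered list of conjunctive rules over numeric features
#' plus a default class. Each rule is a conjunction of conditions of the
#' form `(feature <= t)` or `(feature >= t)`; application is first-match:
#' the first rule whose conditions all hold decides the class, and the
#' default fires only when no rule matches ("Otherwise").
#'
#' @param feature Feature name (may contain spaces).
#' @param relation `"<="` or `">="` (the Unicode forms are accepted on
#'   parsing).
#' @param threshold Finite numeric threshold.
#' @return `condition()` returns a list of class `rule_condition`.
#' @export
condition <- function(feature, relation, threshold) {
  relation <- as.character(relation)
  if (relation == "≤") relation <- "<="
  if (relation == "≥") relation <- ">="
  if (!relation %in% c("<=", ">=")) {
    stopf("condition: relation must be <= or >=")
  }
  if (!is.finite(threshold)) stopf("condition: threshold must be finite")
  structure(list(feature = as.character(feature), relation = relation,
                 threshold = as.numeric(threshold)),
            class = "rule_condition")
}

#' @rdname condition
#' @param conditions List of `condition()` objects (a conjunction); may be
#'   empty only for the default rule.
#' @param outcome Class name the rule predicts.
#' @export
rule <- function(conditions, outcome) {
  structure(list(conditions = conditions, outcome = as.character(outcome)),
            class = "rule")
}

#' @rdname condition
#' @param rules Ordered list of `rule()` objects.
#' @param default_class Class predicted when no rule matches.
#' @export
ruleset <- function(rules, default_class) {
  for (r in rules) {
    if (length(r$conditions) == 0) {
      stopf("ruleset: only the default rule may have no conditions")
    }
  }
  structure(list(rules = rules, default_class = as.character(default_class)),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(format_ruleset(x), sep = "\n")
  invisible(x)
}

#' @export
length.ruleset <- function(x) length(x$rules)

cond_holds <- function(cond, value) {
  if (cond$relation == "<=") value <= cond$threshold else value >= cond$threshold
}

rule_matches_matrix <- function(r, X) {
  out <- rep(TRUE, nrow(X))
  for (cond in r$conditions) {
    if (!cond$feature %in% colnames(X)) {
      stopf("apply_ruleset: sample lacks feature '%s'", cond$feature)
    }
    out <- out & cond_holds(cond, X[, cond$feature])
  }
  out
}

#' Apply a ruleset to samples (first-match semantics)
#'
#' @param rs A [ruleset()].
#' @param samples A named numeric vector (one sample), or a matrix /
#'   data frame / [feature_table()] with named feature columns.
#' @return A list with `class` (character vector of outcomes) and
#'   `rule_index` (1-based index of the fired rule;
#'   `length(rs$rules) + 1` denotes the default).
#' @export
apply_ruleset <- function(rs, samples) {
  if (inherits(samples, "feature_table")) samples <- samples$values
  if (is.null(dim(samples))) {
    samples <- matrix(samples, nrow = 1,
                      dimnames = list(NULL, names(samples)))
  }
  X <- as.matrix(samples)
  n <- nrow(X)
  cls <- rep(rs$default_class, n)
  idx <- rep(length(rs$rules) + 1L, n)
  undecided <- rep(TRUE, n)
  for (i in seq_along(rs$rules)) {
    if (!any(undecided)) break
    m <- rule_matches_matrix(rs$rules[[i]], X)
    fire <- undecided & m
    cls[fire] <- rs$rules[[i]]$outcome
    idx[fire] <- i
    undecided <- undecided & !m
  }
  list(class = cls, rule_index = idx)
}

format_rule <- function(r) {
  if (length(r$conditions) == 0) return(paste0("Otherwise => ", r$outcome))
  conds <- vapply(r$conditions, function(cond) {
    sprintf("(%s %s %s)", cond$feature, cond$relation,
            num_to_string(cond$threshold))
  }, character(1))
  paste0(paste(conds, collapse = " and "), " => ", r$outcome)
}

#' Serialize / parse the rule text format
#'
#' One rule per line, e.g.
#' `(Neuronal stem cell <= 2.58) and (Hepatocyte <= 0) => lncRNA`, with a
#' mandatory final line `Otherwise => <class>`. `format_ruleset` and
#' `parse_ruleset` are mutual inverses.
#'
#' @param rs A [ruleset()].
#' @return `format_ruleset`: character vector of lines.
#' @export
format_ruleset <- function(rs) {
  c(vapply(rs$rules, format_rule, character(1)),
    paste0("Otherwise => ", rs$default_class))
}

#' @rdname format_ruleset
#' @param text Character vector of lines, or a length-1 path to a rule file.
#' @return `parse_ruleset`: a [ruleset()].
#' @export
parse_ruleset <- function(text) {
  if (length(text) == 1 && !grepl("=>", text) && file.exists(text)) {
    text <- readLines(text, encoding = "UTF-8")
  }
  lines <- trimws(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("parse_ruleset: empty rule text")
  last <- lines[length(lines)]
  m <- regmatches(last, regexec("^Otherwise\\s*=>\\s*(.+)$", last))[[1]]
  if (length(m) == 0) {
    stopf("parse_ruleset: missing final 'Otherwise => <class>' line")
  }
  default_class <- trimws(m[2])
  rules <- lapply(lines[-length(lines)], parse_rule_line)
  ruleset(rules, default_class)
}

parse_rule_line <- function(line) {
  parts <- strsplit(line, "=>", fixed = TRUE)[[1]]
  if (length(parts) != 2) stopf("parse_ruleset: malformed rule line: %s", line)
  outcome <- trimws(parts[2])
  lhs <- trimws(parts[1])
  cond_strs <- strsplit(lhs, "\\)\\s+and\\s+\\(")[[1]]
  conds <- lapply(cond_strs, function(cs) {
    cs <- gsub("^\\(|\\)$", "", trimws(cs))
    cm <- regmatches(cs, regexec(
      "^(.*\\S)\\s*(<=|>=|≤|≥)\\s*([-+0-9.eE]+)$", cs))[[1]]
    if (length(cm) == 0) {
      stopf("parse_ruleset: malformed condition '%s' in line: %s", cs, line)
    }
    thr <- suppressWarnings(as.numeric(cm[4]))
    if (is.na(thr)) stopf("parse_ruleset: bad threshold in '%s'", cs)
    condition(trimws(cm[2]), cm[3], thr)
  })
  rule(conds, outcome)
}

#' Write a ruleset to a UTF-8 text file
#'
#' @param rs A [ruleset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rs, path) {
  writeLines(format_ruleset(rs), path, useBytes = FALSE)
  invisible(path)
}
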