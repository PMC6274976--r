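Package: lncpattern
Title: Expression-Pattern Classification of lncRNAs Versus mRNAs Across
    Cell-Type Facets
Version: 1.0.0
Authors@R:
    person("lncpattern", "developers", email = "lncpattern@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting the cross-cell-type expression patterns of
    long noncoding RNAs (lncRNAs) and protein-coding mRNAs from per-facet
    maximum CPM expression tables. Implements coverage-adjusted (Chao-Shen)
    Shannon entropy and a derived expression-specificity score, mRMR
    (minimum-redundancy maximum-relevance) feature ranking, incremental
    feature selection with stratified cross-validation scored by sensitivity,
    specificity, accuracy and the Matthews correlation coefficient, a
    from-scratch RIPPER rule learner producing ordered threshold rules with a
    default class, a randomized-feature-subset significance test, a
    zero-inflated log-normal synthetic data generator with planted
    ground truth, and a pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
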