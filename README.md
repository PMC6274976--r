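# lncpattern

Tools for contrasting the cross-cell-type expression patterns of long
noncoding RNAs (lncRNAs) and protein-coding mRNAs. The input is a labeled
gene-by-feature table — per-transcript maximum CPM expression in each of a
panel of cell-type *facets* (69 in the motivating CAGE atlas), one overall
maximum CPM, and one expression-specificity score — and the package answers
three questions: which facets discriminate lncRNAs from mRNAs, how
separable the two classes are, and what human-readable rules describe the
difference.

For whom: computational biologists who have (or can simulate) such a table
and want an interpretable, reproducible feature-selection-plus-rules
analysis rather than a black-box classifier.

## What it computes

* **Expression specificity** — one minus normalized Chao-Shen-corrected
  Shannon entropy of a transcript's facet profile:
  `spec = 1 − Ĥ/log₂K` with
  `Ĥ = −Σ p̃ᵢ log₂ p̃ᵢ / (1 − (1 − p̃ᵢ)ⁿ)`, `p̃ᵢ = Ĉ cᵢ/n`,
  `Ĉ = 1 − f₁/n`. Higher = more exclusively expressed.
* **mRMR feature ranking** (MID scheme): greedily maximize
  `I(f; class) − mean I(f; selected)` over three-state discretized
  features, plus the relevance-only MaxRel list.
* **Incremental feature selection**: for each prefix of the ranked list,
  stratified 10-fold cross-validation with pooled confusion counts scored
  by SN, SP, ACC and MCC
  (`MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`); the IFS curve,
  its optimal point, and threshold crossings.
* **Classifiers**: an Rcpp random forest (bootstrap + per-split random
  feature subsets + majority vote), a from-scratch RIPPER rule learner
  (FOIL-gain growth, reduced-error pruning, MDL stopping, optimization
  passes) producing ordered `(feature ≤ t)`-style rules with an
  `Otherwise` default, plus 1-NN, linear SVM and logistic baselines.
* **Significance test**: the null distribution of MCCs over random feature
  subsets anchored on the specificity feature, and the sigma excess
  `(observed − mean)/sd` of an observed MCC.
* **Synthetic data**: a zero-inflated log-normal generator with planted
  informative facets and computed specificity, for ground-truth recovery
  tests.

## Worked example

```r
library(lncpattern)

res <- generate_table(synthetic_spec(n_pos = 200, n_neg = 300, seed = 7))
tab <- res$table
tab
#> feature_table: 500 samples (200 lncRNA / 300 mRNA), 71 features

ranking <- mrmr_rank(tab)
print(ranking, n = 5)
#> mrmr feature ranking (71 features)
#>    1. facet_56 (0.0388)
#>    2. facet_08 (0.0364)
#>    3. expression_specificity (0.0347)
#>    4. facet_22 (0.0309)
#>    5. facet_15 (0.0268)
#>   ...

curve <- run_ifs(tab, ranking, classifier_spec("random_forest", seed = 7),
                 k = 10, seed = 7, max_size = 15)
best <- optimal_point(curve)
sprintf("best MCC %.3f with the first %d ranked features",
        best$metrics$MCC, best$size)
#> "best MCC 0.774 with the first 15 ranked features"

rules <- ripper_train(select_features(tab, ranking$order[1:10]),
                      ripper_params(seed = 7))
rules
#> (facet_22 <= 1.773...) and (facet_66 <= 2.742...) and
#>     (expression_specificity >= 0.264...) and ... => lncRNA
#> (facet_08 <= 2.067...) and (facet_42 <= 1.298...) and ... => lncRNA
#> Otherwise => mRNA
```

Reading the output: the ranking scores are mutual-information criterion
values in bits at selection time; the specificity feature lands near the
top because the positive class is generated with more dropout, hence more
exclusive expression. The MCC of 0.774 is the pooled 10-fold value at the
best prefix of the ranked list (this example is a small 500-sample
simulation with a moderate fourfold effect; larger tables and stronger
effects push it above 0.9). The rule list is first-match: a transcript
matching the first rule's conjunction is called lncRNA, anything matching
no rule falls through to mRNA — low expression in a handful of facets plus
high specificity is exactly the published signature shape for lncRNAs.

## Command line

```sh
Rscript inst/cli/lncpattern.R simulate --out table.tsv --seed 1
Rscript inst/cli/lncpattern.R rank     --input table.tsv --out ranked.tsv
Rscript inst/cli/lncpattern.R ifs      --input table.tsv --out ifs.tsv --classifier random_forest
Rscript inst/cli/lncpattern.R rules    --input table.tsv --out rules.txt
Rscript inst/cli/lncpattern.R signif   --input table.tsv --out null.tsv --n-iter 1000
Rscript inst/cli/lncpattern.R run-all  --input table.tsv --out results/ --seed 1
```

`run-all` writes ranked lists, per-classifier IFS curves, an
optimal-classifier summary (algorithm, n features, SN, SP, ACC, MCC), the
trained rule list, the null-distribution table and a JSON manifest that
fully describes the run.

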