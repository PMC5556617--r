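# stabsel

Stability-aware multicriteria selection of sparse predictive models on
high-dimensional data.

## Why

On data with many more features than observations (microarray or RNA-seq
expression matrices, say), very different feature subsets can achieve the
same classification error. A fitted model whose gene list changes completely
under a small perturbation of the data is hard to interpret, however
accurate. stabsel tunes filter + classifier pipelines against **three**
cross-validated criteria at once:

* **error** — mean misclassification rate over the CV folds,
* **size** — mean number of features the fitted models actually use,
* **stability** — similarity of the per-fold selected feature sets
  \(V_1, \dots, V_m \subset \{X_1, \dots, X_p\}\).

and extracts the Pareto-optimal configurations in (1 − stability, size)
among those whose error is within 0.05 of the best observed error
\(c^*\).

## What is implemented

**Nine stability measures** on a `selection_ensemble` (with \(h_j\) the
number of sets containing feature \(j\), \(q = \sum_j h_j\), \(z_i\) the
0/1 indicator vector of \(V_i\)):

* intersection-based: Jaccard `SJ`, Dice `SD`, Ochiai `SO`, and the
  correlation-adjusted `SZ` which also credits *different but highly
  correlated* features across sets;
* chance-corrected: `SL` (expectation-centred intersections), `SS` (relative
  weighted consistency), `SC` (mean Pearson/phi correlation of the
  \(z_i\) — corrected for chance, recommended default);
* frequency-based: `SN` (entropy-type, \(\frac{1}{q\log_2 m}\sum_j h_j
  \log_2 h_j\)) and `SD-α` (\(\max(0, \frac{1}{|V|}\sum_j h_j/m -
  \alpha\,\mathrm{median}|V_i|/p)\)).

**Three filters** (`filter_variance`, `filter_auc`, `filter_mrmr` — greedy
maximum-relevance/minimum-redundancy with AUC relevance and absolute-
correlation redundancy), **four classifier backends** (lasso logistic
regression via glmnet, componentwise logistic gradient boosting, random
forest, RBF-kernel classifier) with their embedded feature-extraction rules,
**stratified k-fold evaluation** (`evaluate_configuration`,
`random_search`), **Pareto tooling** (`dominates`, `pareto_front`,
`accuracy_band`, `desirable_configurations`) and a **synthetic generator**
(`simulate_dataset`) for microarray-like two-class data with correlated
feature blocks.

## Worked example

```r
library(stabsel)
library(dplyr)

d <- simulate_dataset(n = 100, p = 50, n_informative = 3, effect = 2.5, seed = 42)
sr <- random_search(d, n_configs = 24, folds = 10, seed = 7)
glance(sr)
#> # A tibble: 1 × 6
#>   n_configs n_failed folds     n     p c_star
#>       <int>    <int> <dbl> <int> <int>  <dbl>
#> 1        24        0    10   100    50   0.01

desirable_configurations(sr, measure = "SC") |>
  select(config_id, filter, n_feats, classifier, error, size, SC)
#> # A tibble: 2 × 7
#>   config_id filter   n_feats classifier error  size    SC
#>       <int> <chr>      <int> <chr>      <dbl> <dbl> <dbl>
#> 1         5 variance       8 rf          0.01   8   0.864
#> 2        18 mrmr          14 glmboost    0.01   7.6 0.735
```

Reading: among 24 random configurations the best 10-fold CV error is
`c_star = 0.01`; inside the `c* + 0.05` accuracy band, two configurations
are Pareto-optimal in (1 − SC, size) — e.g. a variance-filtered random
forest that uses 8 features on average with selection stability `SC = 0.86`
(1 = the same features in every fold, 0 = chance-level overlap).

Individual ensembles can be scored directly:

```r
ens <- selection_ensemble(list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 3)), p = 1000)
stability_all(ens, alphas = c(0, 1))
#>    measure  value lower upper note
#>  1 SJ       0.667     0 1     NA
#>  2 SD       0.778     0 1     NA
#>  ...
#>  8 SC       0.777    -1 1     NA
```

Measures whose preconditions fail (empty sets, all features selected, no
correlation matrix for `SZ`) come back as `NA` with an explanatory note,
never as a silent 0.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch against the
installed package: it simulates the default microarray-like world
(n = 150, p = 300, 5 informative features, one correlated block), runs a
random hyperparameter search over the 12 filter × classifier combinations
with 10-fold cross-validation, applies the `c* + 0.05` accuracy band and
extracts the stability/size Pareto fronts, then writes its JSON report to
`--out`. All randomness derives from `--seed`.

See `vignettes/stability-aware-model-selection.Rmd` for the measures'
definitions, the numerical conventions (tie-breaking, thresholds, degenerate
cases) and the generator's scope.
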