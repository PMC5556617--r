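---
title: "Stability-aware multicriteria model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-aware multicriteria model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(stabsel)
library(dplyr)
```

## The problem

On high-dimensional data — thousands of gene-expression features, a few
hundred samples — many different feature subsets yield near-identical
predictive accuracy. A model that is re-fitted on a slightly perturbed data
set and selects a completely different gene list is hard to interpret and
hard to trust, even if its error rate is unchanged. *Feature-selection
stability* quantifies this reproducibility: a selection procedure is stable
if the feature sets \(V_1, \dots, V_m \subset \{X_1, \dots, X_p\}\) it picks
on \(m\) resampled versions of the data are similar.

stabsel treats classifier tuning as a multicriteria problem over three
cross-validated quantities per configuration (a filter, the number of
features it keeps, a classifier, and its hyperparameters):

* **error** — mean misclassification rate over the CV folds;
* **size** — mean number of features the fitted models actually use;
* **stability** — similarity of the per-fold feature sets, under one of nine
  measures.

Desirable configurations are Pareto-optimal in (1 − stability, size) among
the configurations whose error stays within a band of the best observed
error.

## The stability measures

With \(h_j\) the number of sets containing feature \(j\),
\(q = \sum_j h_j\), and \(z_i \in \{0,1\}^p\) the indicator vector of
\(V_i\), the implemented measures are:

| id | idea | range | corrected for chance |
|----|------|-------|----------------------|
| `SJ` | mean pairwise Jaccard index \(|V_i \cap V_j| / |V_i \cup V_j|\) | [0, 1] | no |
| `SD` | mean pairwise Dice coefficient | [0, 1] | no |
| `SO` | mean pairwise Ochiai coefficient | [0, 1] | no |
| `SZ` | Jaccard credit extended to *correlated* cross-set features | [0, 1] | no |
| `SL` | pairwise intersection centred by its random-selection expectation | [−1, 1] | yes |
| `SN` | entropy-type score of the selection frequencies \(h_j\) | [0, 1] | no |
| `SD-α` | frequency reward minus α · median model size / p | [0, max(1 − α/p, 1/(m(m−1)/2))] | no (size-corrected) |
| `SS` | relative weighted consistency of the \(h_j\), rescaled by q-dependent bounds | [0, 1] | yes |
| `SC` | mean pairwise Pearson correlation of the \(z_i\) (phi coefficient) | [−1, 1] | yes |

Correction for chance matters because an uncorrected measure grows
mechanically with the number of selected features: two random 9,000-feature
subsets of 10,000 overlap hugely by pigeonhole alone. The acceptance tests
verify this Monte-Carlo: under uniformly random \(k\)-subsets the mean of
`SC` stays within three standard errors of 0 for every \(k\), while `SJ`,
`SD`, `SO` and `SN` increase strictly with \(k\).

```{r}
ens <- selection_ensemble(list(c(1, 2, 3), c(1, 2, 4), c(1, 2, 3)), p = 1000)
stability_all(ens, alphas = c(0, 1))
```

## Numerical and design choices

Decisions the definitions leave open, fixed and documented here:

* **Correlation threshold in `SZ`.** The indicator over the interval
  \((r_{ij}, \infty)\) is read as a *strict* inequality
  \(\mathrm{Cor}(x, y) > r_{ij}\), with \(r_{ij}\) the median correlation
  over distinct feature pairs in \(V_i \cup V_j\). One consequence: when the
  union has exactly two features, the single correlation never exceeds its
  own median, so the pair score reduces to Jaccard. `strict = FALSE`
  switches to `>=`.
* **Empty sets.** No measure evaluates an ensemble containing an empty set;
  a typed `stabsel_error_empty_set` is raised instead of guessing a value
  (denominators such as \(|V_i \cup V_j|\) vanish). `stability_all()` maps
  such errors to `NA` plus a note, so sweeps never abort.
* **Degenerate denominators.** `SL` (pair denominator 0), `SS`
  (\(c_{\min} = c_{\max}\)) and `SC` (constant indicator) are undefined when
  every feature is selected; they raise `stabsel_error_degenerate_selection`
  and are reported as undefined, never imputed as 0.
* **Medians** are standard sample medians (mean of the two central order
  statistics for even \(m\)).
* **Ties** in filter scores are always broken by the lowest feature index.
  This makes selection deterministic, which matters because tie-breaking
  directly affects measured stability.
* **MRMR first step.** Redundancy over an empty chosen set is undefined, so
  the first pick maximises relevance (the AUC filter score). A later
  candidate with redundancy exactly 0 gets quotient \(+\infty\); such
  candidates are ranked among themselves by relevance. The often-claimed
  monotone decrease of the greedy quotient is *not* assumed: all candidate
  quotients are recomputed every step (the tests check the claim empirically
  but the implementation never relies on it).
* **Misclassification** uses a 0.5 threshold on the positive-class score of
  probabilistic classifiers.
* **CV folds are stratified** by class. The definitions are silent on this;
  stratification keeps the class balance in every fold and stabilises the
  per-fold error estimates, at the price of a split distribution that is not
  exactly uniform over all partitions.
* **Correlation context for `SZ` inside CV** is computed once from the full
  data matrix, so every fold pair shares one correlation notion; computing
  it per pair on fold unions would silently change the median threshold.
  Pass `cor` explicitly to override.
* **"Equals the theoretical maximum"** assertions in the tests use an
  absolute tolerance of 1e-9.

## Classifier backends and feature extraction

Classifiers plug in behind a small contract — fit on a training matrix,
score held-out rows, report the features the fitted model *uses*:

* lasso logistic regression (glmnet): features with nonzero coefficients at
  penalty λ;
* componentwise logistic gradient boosting with linear base learners:
  features whose base learner is picked in at least one of `m_stop`
  iterations (own Rcpp implementation; learning rate 0.1);
* random forest (own Rcpp implementation; bootstrap, Gini splits,
  `mtry = floor(sqrt(p))`): features with impurity importance strictly
  greater than 0;
* RBF-kernel classifier with parameters σ and C: uses all supplied
  features. No quadratic-programming SVM solver is available in the target
  environment, so this backend is fitted by kernel ridge regression on the
  ±1 class coding with penalty 1/C — it fills the same niche (a non-sparse
  kernel method with the same two hyperparameters and the same
  all-features extraction rule), but its decision values are not those of a
  max-margin SVM.

The hyperparameter search space follows the conventional log/linear ranges:
`n_feats` uniform on {1..p}; `m_stop`, `num_trees` uniform on {1..2^15};
`min_node_size` uniform on {1..2^5}; λ, σ, C drawn as \(2^x\) with
\(x \sim U[-15, 15]\).

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces the stated testing world: `n = 150`
observations, `p = 300` standard-normal features, 5 informative features
whose class means differ by 2 noise-SDs, one block of 10 features with
pairwise correlation 0.9 built from a shared latent factor
(\(x = \sqrt{\rho} f + \sqrt{1-\rho}\,\epsilon\), which hits the target
correlation exactly in population), and balanced Bernoulli class labels.
These defaults are a deliberately desk-scale analogue of two-class
microarray studies: many features, few discriminative ones, co-expressed
gene blocks that motivate the correlation-adjusted stability measure.

It does **not** emulate count-valued RNA-seq data (no negative-binomial
noise), batch effects, missing values, or heavy-tailed expression
distributions. A green end-to-end test therefore establishes that the
machinery behaves as designed under Gaussian, block-correlated signal — it
does not certify performance claims on any real data set.

```{r}
d <- simulate_dataset(n = 100, p = 50, n_informative = 3, seed = 42)
filter_auc(d) |> select_top_k(k = 5)
```

## The multicriteria analysis

```{r, eval = FALSE}
search <- random_search(d, n_configs = 60, folds = 10, seed = 7)
band <- accuracy_band(tidy(search), delta = 0.05)
front <- desirable_configurations(search, measure = "SC", delta = 0.05)
autoplot(search, measure = "SC")
```

The accuracy band retains configurations with error at most
\(c^* + 0.05\), where \(c^*\) is the best error among *all* evaluated
configurations (a single global \(c^*\), not one per augmented method — the
band is meant to anchor every method to the same attainable accuracy).
`mode = "3d"` skips the band and takes the Pareto front over all three
criteria directly. Duplicate criteria vectors are all kept on the front:
when dozens of configurations collapse onto one point, their provenance is
the interesting part. The front algorithm is a plain \(O(n^2)\) dominance
scan — for the tens of thousands of points seen here, nothing cleverer is
warranted.

Within a random search all configurations share one stratified CV split, so
their criteria are directly comparable, and filter rankings are computed
once per (fold, filter) pair: top-\(k\) selections are nested in \(k\)
(greedy forward selection makes MRMR orders prefix-stable), so each
configuration slices a prefix. Both are exact optimisations, not
approximations.

## Known limitations

* Stability values compare configurations *on the same data set*; they are
  not calibrated across data sets or resampling designs.
* The chance-corrected measures are undefined when a model uses all (or no)
  features; such configurations are excluded from that measure's front with
  a warning.
* The random-forest and boosting backends are compact reimplementations
  tuned for many small fits; they follow the standard algorithms but will
  not numerically match ranger or mboost fit-for-fit.
* Random search is the only tuner; no model-based optimisation is provided.
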