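Package: stabsel
Title: Stability-Aware Multicriteria Selection of Sparse Predictive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning classifiers on high-dimensional data when the
    reproducibility of the selected features matters as much as predictive
    accuracy. Implements nine feature-selection stability measures
    (intersection-, frequency- and correlation-based, with and without
    correction for chance), variance, AUC and greedy
    minimum-redundancy-maximum-relevance (MRMR) filters, cross-validated
    evaluation of filter-plus-classifier configurations against
    misclassification rate, model size and stability, random hyperparameter
    search, and Pareto-front extraction of desirable configurations within an
    accuracy band. Includes a synthetic generator for microarray-like data
    (many features, few informative, correlated blocks) so every analysis is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
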