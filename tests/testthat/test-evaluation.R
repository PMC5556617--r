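small_data <- function(seed = 7) {
  simulate_dataset(n = 60, p = 20, n_informative = 2, effect = 2.5,
                   blocks = list(), seed = seed)
}

test_that("cv_splits partitions rows into stratified near-equal folds", {
  y <- factor(rep(c("a", "b"), times = c(60, 40)))
  sp <- cv_splits(y, folds = 10, seed = 1)
  tests <- lapply(sp, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100) # partition
  expect_true(all(lengths(tests) == 10))
  for (s in sp) {
    expect_setequal(c(s$train, s$test), 1:100) # complementary
    expect_equal(sum(y[s$test] == "a"), 6) # stratification
  }
  # sizes differ by <= 1 when n is not a multiple of folds
  y2 <- factor(rep(c("a", "b"), times = c(13, 14)))
  sizes <- lengths(lapply(cv_splits(y2, 5, seed = 2), `[[`, "test"))
  expect_lte(diff(range(sizes)), 1)
  # determinism
  expect_identical(cv_splits(y, 10, seed = 3), cv_splits(y, 10, seed = 3))
  expect_false(identical(cv_splits(y, 10, seed = 3), cv_splits(y, 10, seed = 4)))
  expect_error(cv_splits(y[1:5], folds = 6), class = "stabsel_error_shape")
})

test_that("configuration validates hyperparameters against their ranges", {
  cfg <- configuration("auc", 5, classifier = "lasso", lambda = 0.1)
  expect_s3_class(cfg, "stab_config")
  expect_error(
    configuration("auc", 5, classifier = "lasso", lambda = 2^16),
    class = "stabsel_error_config"
  )
  expect_error(
    configuration("auc", 5, classifier = "glmboost", m_stop = 1.5),
    class = "stabsel_error_config"
  )
  expect_error(
    configuration("auc", 5, classifier = "glmboost"),
    class = "stabsel_error_config" # missing hyperparameter
  )
  expect_error(
    configuration("auc", 5, classifier = "lasso", lambda = 1, sigma = 1),
    class = "stabsel_error_config" # unknown hyperparameter
  )
  expect_error(
    configuration("auc", n_feats = NULL, classifier = "lasso", lambda = 1),
    class = "stabsel_error_config"
  )
})

test_that("feature-set extraction follows each backend's rule", {
  d <- small_data()
  # SVM uses all features
  svm <- fit_and_extract(
    d, configuration("none", classifier = "svm", sigma = 0.01, C = 1)
  )
  expect_equal(svm$selected, 1:20)
  # the filter caps the cascade
  one <- fit_and_extract(
    d, configuration("auc", 1, classifier = "rf", num_trees = 50, min_node_size = 1)
  )
  expect_true(all(one$selected %in% one$filtered))
  expect_length(one$filtered, 1)
  # an extreme lasso penalty empties the model
  heavy <- fit_and_extract(
    d, configuration("none", classifier = "lasso", lambda = 2^15)
  )
  expect_length(heavy$selected, 0)
  # moderate penalty: nonzero coefficients only
  mid <- fit_and_extract(
    d, configuration("none", classifier = "lasso", lambda = 0.05)
  )
  expect_gt(length(mid$selected), 0)
  # boosting with few iterations uses at most m_stop base learners
  bo <- fit_and_extract(
    d, configuration("none", classifier = "glmboost", m_stop = 3)
  )
  expect_lte(length(bo$selected), 3)
})

test_that("evaluation aggregates fold errors and sizes exactly", {
  d <- small_data()
  cfg <- configuration("auc", 4, classifier = "lasso", lambda = 0.05)
  ev <- evaluate_configuration(d, cfg, folds = 5, seed = 11)
  expect_equal(ev$error, mean(ev$fold_errors), tolerance = 1e-12)
  expect_equal(ev$size, mean(ens_sizes(ev$ensemble)))
  expect_length(ev$ensemble, 5)
  expect_true(all(ev$fold_errors >= 0 & ev$fold_errors <= 1))
  g <- glance(ev)
  expect_equal(g$error, ev$error)
  expect_equal(tidy(ev), ev$stability)
})

test_that("a deterministic easy problem yields a perfectly stable sparse model", {
  # one hugely informative feature; auc filter with n_feats = 1 must find it
  # in every fold and the classifier then separates perfectly
  d <- simulate_dataset(n = 80, p = 15, n_informative = 1, effect = 8,
                        blocks = list(), seed = 23)
  cfg <- configuration("auc", 1, classifier = "lasso", lambda = 0.01)
  ev <- evaluate_configuration(d, cfg, folds = 5, seed = 2)
  expect_equal(ev$error, 0)
  expect_equal(ev$size, 1)
  val <- function(id) ev$stability$value[ev$stability$measure == id]
  expect_equal(val("SJ"), 1)
  expect_equal(val("SC"), 1)
  expect_equal(val("SN"), 1)
})

test_that("no information leaks from held-out rows into fitting or selection", {
  d <- small_data(31)
  sp <- cv_splits(d$class, folds = 4, seed = 5)
  cfg <- configuration("auc", 3, classifier = "lasso", lambda = 0.05)
  tr <- d[sp[[1]]$train, ]
  te <- d[sp[[1]]$test, ]
  f1 <- fit_and_extract(tr, cfg, newdata = te)
  te_mut <- te
  te_mut[, -1] <- te_mut[, -1] * 5 + 7
  f2 <- fit_and_extract(tr, cfg, newdata = te_mut)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$filtered, f2$filtered)
})

test_that("sampled configurations respect the search space and seeds", {
  space <- config_space(p = 50)
  cfgs <- sample_configurations(space, n = 24, seed = 9)
  expect_equal(nrow(cfgs), 24L)
  expect_true(all(cfgs$n_feats >= 1 & cfgs$n_feats <= 50))
  expect_true(all(cfgs$filter %in% c("variance", "auc", "mrmr")))
  ok <- is.na(cfgs$lambda) | (cfgs$lambda >= 2^-15 & cfgs$lambda <= 2^15)
  expect_true(all(ok))
  expect_true(all(is.na(cfgs$m_stop) | cfgs$m_stop == round(cfgs$m_stop)))
  # every classifier carries exactly its own hyperparameters
  expect_true(all(!is.na(cfgs$m_stop[cfgs$classifier == "glmboost"])))
  expect_true(all(is.na(cfgs$m_stop[cfgs$classifier != "glmboost"])))
  # 24 configs over 12 augmented methods = 2 each
  expect_true(all(table(cfgs$filter, cfgs$classifier) == 2))
  expect_identical(
    sample_configurations(space, 10, seed = 4),
    sample_configurations(space, 10, seed = 4)
  )
  per <- sample_configurations(space, n = 2, per_method = TRUE, seed = 1)
  expect_equal(nrow(per), 24L)
})

test_that("random_search reproduces evaluate_configuration on shared splits", {
  d <- small_data(41)
  set.seed(77)
  sr <- random_search(d, n_configs = 12, folds = 4, seed = 19)
  res <- tidy(sr)
  expect_equal(nrow(res), 12L)
  expect_true(all(is.na(res$note)))
  # re-evaluate one configuration with the same splits: identical criteria
  set.seed(19)
  cfgs <- sample_configurations(config_space(20), 12)
  splits <- cv_splits(d$class, 4)
  pick <- which(res$classifier == "lasso")[1]
  cfg <- configuration(
    res$filter[pick], res$n_feats[pick],
    classifier = "lasso", lambda = res$lambda[pick]
  )
  refit <- stabsel:::eval_with_rankings(
    d, cfg, "class", splits,
    lapply(seq_len(4), function(f) {
      tr <- d[splits[[f]]$train, ]
      list(
        variance = stabsel:::ranked_indices(filter_variance(tr)),
        auc = stabsel:::ranked_indices(filter_auc(tr)),
        mrmr = stabsel:::mrmr_ranked(tr, "class", 20)
      )
    }),
    feature_correlations(d), names(stabsel:::measure_registry()), c(0, 1, 2, 10)
  )
  expect_equal(refit$error, res$error[pick], tolerance = 1e-12)
  expect_equal(refit$size, res$size[pick], tolerance = 1e-12)
  # determinism of the whole sweep
  sr2 <- random_search(d, n_configs = 12, folds = 4, seed = 19)
  expect_equal(tidy(sr2), res)
  g <- glance(sr)
  expect_equal(g$c_star, min(res$error))
})

test_that("sweeps can be restricted to a subset of stability measures", {
  d <- small_data(51)
  sr <- random_search(d, n_configs = 6, folds = 3, seed = 3,
                      measures = c("SJ", "SC"))
  expect_true(all(c("SJ", "SC") %in% names(tidy(sr))))
  expect_false("SN" %in% names(tidy(sr)))
})
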