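toy_data <- function(x_cols, y) {
  d <- tibble::as_tibble(x_cols)
  d$class <- factor(y)
  d
}

test_that("variance filter scores are exact sample variances", {
  d <- toy_data(list(a = c(0, 2), b = c(1, 1), c = c(-3, 3)), c("u", "v"))
  fs <- filter_variance(d)
  expect_equal(fs$score, c(2, 0, 18)) # n - 1 denominator; constants score 0
  # variance homogeneity: scaling by c multiplies the score by c^2
  d2 <- d
  d2$a <- 3 * d2$a
  expect_equal(filter_variance(d2)$score[1], 9 * fs$score[1])
  expect_error(
    filter_variance(toy_data(list(a = 1), "u")),
    class = "stabsel_error_shape"
  )
})

test_that("AUC filter handles separation, anti-separation and ties", {
  y <- c(0, 0, 1, 1)
  perfect <- toy_data(list(a = c(1, 2, 5, 6)), y)
  expect_equal(filter_auc(perfect)$score, 0.5)
  anti <- toy_data(list(a = c(5, 6, 1, 2)), y)
  expect_equal(filter_auc(anti)$score, 0.5) # AUC 0 is as good as AUC 1
  tied <- toy_data(list(a = c(1, 2, 1, 2)), y)
  expect_equal(filter_auc(tied)$score, 0) # midrank AUC = 0.5
  expect_error(
    filter_auc(toy_data(list(a = 1:4), c(1, 1, 1, 1))),
    class = "stabsel_error_single_class"
  )
})

test_that("AUC filter is invariant under strictly increasing transforms", {
  set.seed(21)
  d <- simulate_dataset(n = 60, p = 6, n_informative = 2, blocks = list(), seed = 21)
  base <- filter_auc(d)$score
  d2 <- d
  for (j in 2:7) d2[[j]] <- exp(d2[[j]]) # monotone transform of every feature
  expect_equal(filter_auc(d2)$score, base, tolerance = 1e-12)
})

test_that("MRMR picks the relevance-maximal feature first, then low redundancy", {
  # f1 separates perfectly, f2 duplicates f1 (correlation 1), f3 is a weaker
  # separator nearly uncorrelated with f1
  y <- rep(c(0, 1), each = 6)
  f1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  f3 <- c(3, 9, 1, 8, 2, 5, 9, 2, 8, 10, 3, 10)
  d <- toy_data(list(f1 = f1, f2 = f1, f3 = f3), y)
  fs <- filter_mrmr(d, k = 3)
  rel <- fs$score
  # the scenario the greedy quotient rule is meant to resolve really holds:
  expect_true(rel[1] == max(rel) && rel[3] < rel[1])
  c13 <- abs(stats::cor(f1, f3))
  expect_true(rel[3] / c13 > rel[2] / 1) # f3's quotient beats the duplicate's
  ord <- fs$index[order(fs$rank)]
  expect_equal(ord[1:2], c(1L, 3L))
  expect_equal(fs$quotient[fs$rank == 1], Inf)

  # k = 1 degenerates to the AUC-filter argmax
  f1only <- filter_mrmr(d, k = 1)
  expect_equal(f1only$index[!is.na(f1only$rank)], which.max(filter_auc(d)$score))

  # identical features: every later quotient ties, broken by lowest index
  dd <- toy_data(list(a = f1, b = f1, c = f1, d = f1), y)
  oo <- filter_mrmr(dd)
  expect_equal(oo$index[order(oo$rank)], 1:4)
})

test_that("MRMR with k = p permutes all features and nests over k", {
  d <- simulate_dataset(n = 50, p = 10, n_informative = 2, blocks = list(), seed = 5)
  full <- filter_mrmr(d)
  ordfull <- full$index[order(full$rank)]
  expect_setequal(ordfull, 1:10)
  expect_equal(ordfull[1], which.max(filter_auc(d)$score))
  part <- filter_mrmr(d, k = 4)
  expect_equal(part$index[order(part$rank, na.last = NA)], ordfull[1:4])
  # empirical check (not an assumption): quotient trajectory is finite after
  # the first pick
  expect_true(all(is.finite(full$quotient[full$rank > 1])))
})

test_that("select_top_k is deterministic, nested, and supports thresholds", {
  fs <- structure(
    tibble::tibble(index = 1:3, feature = c("a", "b", "c"), score = c(3, 1, 2)),
    class = c("filter_scores", class(tibble::tibble())), filter = "variance"
  )
  expect_equal(select_top_k(fs, k = 2), c(1L, 3L))
  expect_equal(select_top_k(fs, k = 3), 1:3)
  ties <- fs
  ties$score <- c(1, 1, 1)
  expect_equal(select_top_k(ties, k = 1), 1L)
  expect_equal(select_top_k(fs, threshold = 1.5), c(1L, 3L))
  expect_error(select_top_k(fs, k = 4), class = "stabsel_error_shape")
  expect_error(select_top_k(fs), class = "stabsel_error_config")
  # nestedness over k
  set.seed(2)
  d <- simulate_dataset(n = 40, p = 15, seed = 2)
  sc <- filter_auc(d)
  for (k in 1:14) {
    expect_true(all(select_top_k(sc, k = k) %in% select_top_k(sc, k = k + 1)))
  }
})

test_that("filters depend only on the rows they are fitted on", {
  d <- simulate_dataset(n = 60, p = 20, seed = 13)
  train <- d[1:40, ]
  mutated <- d
  mutated[41:60, -1] <- mutated[41:60, -1] + 100 # perturb held-out rows only
  for (f in list(filter_variance, filter_auc, function(x) filter_mrmr(x, k = 5))) {
    expect_identical(f(train), f(mutated[1:40, ]))
  }
})
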