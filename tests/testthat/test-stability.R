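ens2 <- function(a, b, p) selection_ensemble(list(a, b), p = p)

test_that("intersection-based measures reproduce hand-computed values", {
  e <- ens2(c(1, 2), c(1, 3), p = 10)
  expect_equal(stability_jaccard(e), 1 / 3)
  expect_equal(stability_dice(e), 0.5)
  expect_equal(stability_ochiai(ens2(c(1, 2), 1, p = 10)), 1 / sqrt(2))

  ident <- selection_ensemble(list(c(2, 5), c(2, 5), c(2, 5)), p = 9)
  expect_equal(stability_jaccard(ident), 1)
  expect_equal(stability_dice(ident), 1)
  expect_equal(stability_ochiai(ident), 1)

  disj <- ens2(c(1, 2), c(3, 4), p = 6)
  expect_equal(stability_jaccard(disj), 0)
  expect_equal(stability_dice(disj), 0)
  expect_equal(stability_ochiai(disj), 0)
})

test_that("chance-corrected and frequency-based measures reproduce hand values", {
  expect_equal(stability_lustgarten(ens2(1, 1, p = 4)), 0.75)
  expect_equal(stability_lustgarten(ens2(1, 2, p = 4)), -0.25)
  expect_equal(stability_novovicova(ens2(1, 2, p = 5)), 0)
  expect_equal(stability_novovicova(ens2(c(1, 2), 1, p = 5)), 2 / 3)
  expect_equal(
    stability_novovicova(selection_ensemble(list(1:3, 1:3), p = 8)), 1
  )
  expect_equal(stability_davis(ens2(c(1, 2), c(1, 3), p = 10), alpha = 0), 2 / 3)
  det2 <- ens2(c(1, 2), c(1, 2), p = 10)
  expect_equal(stability_davis(det2, alpha = 1), 0.8)
  expect_equal(stability_davis(det2, alpha = 10), 0) # clamped at 0
  expect_equal(stability_somol(ens2(1, 1, p = 4)), 1)
  expect_equal(stability_somol(ens2(1, 2, p = 4)), 0)
  expect_equal(stability_somol(ens2(c(1, 2), 1, p = 4)), 1)
  expect_equal(stability_correlation(ens2(1, 2, p = 2)), -1)
  expect_equal(stability_correlation(ens2(c(1, 2), c(1, 3), p = 4)), 0)
})

test_that("correlation-adjusted measure handles thresholding and reduces to Jaccard", {
  cc <- diag(3)
  cc[2, 3] <- cc[3, 2] <- 0.9
  cc[1, 2] <- cc[2, 1] <- cc[1, 3] <- cc[3, 1] <- 0.1
  e <- ens2(c(1, 2), c(1, 3), p = 3)
  expect_equal(stability_zucknick(e, cc), (1 + 0.45 + 0.45) / 3)

  # zero off-diagonal correlations: no adjustment, equals Jaccard
  p <- 8
  set.seed(4)
  for (rep in 1:10) {
    sets <- rand_ens_sets(m = 4, p = p)
    ens <- selection_ensemble(sets, p = p)
    expect_equal(stability_zucknick(ens, diag(p)), stability_jaccard(ens))
  }

  # identical sets attain the maximum regardless of correlations
  ident <- selection_ensemble(list(c(1, 3), c(1, 3)), p = 3)
  expect_equal(stability_zucknick(ident, cc), 1)

  # undefined correlations among selected features are rejected
  cc[2, 3] <- cc[3, 2] <- NA
  expect_error(
    stability_zucknick(e, cc),
    class = "stabsel_error_undefined_correlation"
  )
})

test_that("pairwise measures equal the brute-force oracle on random ensembles", {
  set.seed(42)
  for (rep in 1:120) {
    p <- sample(4:12, 1)
    m <- sample(2:6, 1)
    sets <- rand_ens_sets(m, p)
    ens <- selection_ensemble(sets, p = p)
    cormat <- suppressWarnings(stats::cor(matrix(rnorm(20 * p), 20, p)))
    alpha <- sample(c(0, 1, 2, 10), 1)
    expect_equal(stability_jaccard(ens), oracle_jaccard(sets, p), tolerance = 1e-12)
    expect_equal(stability_dice(ens), oracle_dice(sets, p), tolerance = 1e-12)
    expect_equal(stability_ochiai(ens), oracle_ochiai(sets, p), tolerance = 1e-12)
    expect_equal(stability_lustgarten(ens), oracle_lustgarten(sets, p), tolerance = 1e-12)
    expect_equal(stability_zucknick(ens, cormat), oracle_zucknick(sets, p, cormat), tolerance = 1e-12)
    expect_equal(stability_novovicova(ens), oracle_novovicova(sets, p), tolerance = 1e-12)
    expect_equal(stability_davis(ens, alpha), oracle_davis(sets, p, alpha), tolerance = 1e-12)
    expect_equal(stability_somol(ens), oracle_somol(sets, p), tolerance = 1e-12)
    expect_equal(stability_correlation(ens), oracle_correlation(sets, p), tolerance = 1e-12)
  }
})

test_that("pairwise identities hold: Dice-Jaccard relation and phi equivalence", {
  set.seed(7)
  for (rep in 1:50) {
    p <- sample(4:12, 1)
    sets <- rand_ens_sets(2, p)
    ens <- selection_ensemble(sets, p = p)
    jac <- stability_jaccard(ens)
    expect_equal(stability_dice(ens), 2 * jac / (1 + jac), tolerance = 1e-12)
    # phi from the 2x2 contingency table of the indicator vectors
    z <- ens_indicator(ens)
    a <- sum(z[1, ] == 1 & z[2, ] == 1)
    b <- sum(z[1, ] == 1 & z[2, ] == 0)
    c_ <- sum(z[1, ] == 0 & z[2, ] == 1)
    d <- sum(z[1, ] == 0 & z[2, ] == 0)
    phi <- (a * d - b * c_) / sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(stability_correlation(ens), phi, tolerance = 1e-12)
  }
})

test_that("all measures stay inside their theoretical ranges", {
  set.seed(11)
  for (rep in 1:400) {
    p <- sample(4:12, 1)
    m <- sample(2:6, 1)
    ens <- selection_ensemble(rand_ens_sets(m, p), p = p)
    res <- stability_all(ens, cor = diag(p))
    ok <- !is.na(res$value)
    expect_true(all(res$value[ok] >= res$lower[ok] - 1e-9))
    expect_true(all(res$value[ok] <= res$upper[ok] + 1e-9))
  }
})

test_that("degenerate ensembles raise typed errors and are routed by stability_all", {
  p <- 6
  full <- selection_ensemble(list(1:p, 1:p), p = p)
  expect_error(stability_lustgarten(full), class = "stabsel_error_degenerate_selection")
  expect_error(stability_somol(full), class = "stabsel_error_degenerate_selection")
  expect_error(stability_correlation(full), class = "stabsel_error_degenerate_selection")

  hollow <- selection_ensemble(list(integer(0), 2), p = p)
  for (f in list(
    stability_jaccard, stability_dice, stability_ochiai,
    stability_lustgarten, stability_novovicova, stability_somol,
    stability_correlation
  )) {
    expect_error(f(hollow), class = "stabsel_error_empty_set")
  }
  expect_error(stability_davis(hollow, 1), class = "stabsel_error_empty_set")

  res <- stability_all(full, cor = diag(p))
  undef <- res$measure[is.na(res$value)]
  expect_setequal(undef, c("SL", "SS", "SC"))
  expect_true(all(!is.na(res$note[is.na(res$value)])))
  # uncorrected measures still evaluate to their maximum
  expect_equal(res$value[res$measure == "SJ"], 1)
})

test_that("stability_all agrees with the individual measures and honours subsets", {
  set.seed(3)
  p <- 10
  ens <- selection_ensemble(rand_ens_sets(4, p), p = p)
  cormat <- suppressWarnings(stats::cor(matrix(rnorm(30 * p), 30, p)))
  res <- stability_all(ens, cor = cormat, alphas = c(0, 2))
  val <- function(id) res$value[res$measure == id]
  expect_equal(val("SJ"), stability_jaccard(ens))
  expect_equal(val("SZ"), stability_zucknick(ens, cormat))
  expect_equal(val("SS"), stability_somol(ens))
  expect_equal(val("SD-2"), stability_davis(ens, 2))
  sub <- stability_all(ens, measures = c("SJ", "SC"))
  expect_equal(sub$measure, c("SJ", "SC"))
})
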