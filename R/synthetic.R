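#' Simulate a microarray-like labeled data set
#'
#' Generates a two-class data set with the structure the package's analyses
#' assume: many metric features, few of them informative, optional blocks of
#' correlated features (emulating co-expressed genes), and standard normal
#' noise everywhere else.
#'
#' Class labels are drawn as independent Bernoulli(`balance`) (redrawn in the
#' rare event that one class is empty). Each informative feature receives a
#' class-dependent mean shift of `+effect/2` / `-effect/2` noise-SD units.
#' Each correlated block is built from a shared latent factor,
#' \eqn{x = \sqrt{\rho} f + \sqrt{1 - \rho}\,\epsilon}, which gives an exact
#' population pairwise correlation of `rho` within the block. Blocks occupy
#' the features immediately after the informative ones unless
#' `blocks_informative = TRUE`, in which case they overlap the informative
#' indices, producing "different but highly correlated" features whose
#' interchangeable selection distinguishes the correlation-adjusted stability
#' measure from the plain Jaccard measure.
#'
#' The defaults are the desk-scale testing world used throughout the package:
#' `n = 150`, `p = 300`, five informative features with a shift of two
#' noise-SDs, one block of ten features at correlation 0.9, balanced classes.
#'
#' @param n,p Number of observations and features.
#' @param n_informative Number of class-associated features (indices `1:n_informative`).
#' @param effect Class-mean separation on informative features, in noise-SD units.
#' @param blocks List of `c(size, rho)` pairs describing correlated blocks.
#' @param balance Probability of class `"pos"`.
#' @param blocks_informative Overlap the correlated blocks with the
#'   informative features instead of placing them after.
#' @param seed Optional integer seed; the generator is fully reproducible.
#'
#' @return A tibble with a two-level factor column `class` (levels `"neg"`,
#'   `"pos"`) and feature columns `f001`, `f002`, ... Attributes:
#'   `informative` (integer indices of the informative features) and `spec`
#'   (the generator parameters).
#' @examples
#' d <- simulate_dataset(n = 60, p = 20, n_informative = 3, seed = 42)
#' attr(d, "informative")
#' @export
simulate_dataset <- function(n = 150, p = 300, n_informative = 5, effect = 2,
                             blocks = list(c(size = 10, rho = 0.9)),
                             balance = 0.5, blocks_informative = FALSE,
                             seed = NULL) {
  if (n_informative > p) {
    stop_config("`n_informative` must not exceed `p`.")
  }
  if (balance <= 0 || balance >= 1) {
    stop_config("`balance` must lie strictly between 0 and 1.")
  }
  blocks <- lapply(blocks, function(b) {
    size <- as.integer(b[["size"]])
    rho <- as.numeric(b[["rho"]])
    if (is.na(size) || size < 2L) stop_config("Block sizes must be >= 2.")
    if (is.na(rho) || rho < 0 || rho >= 1) stop_config("Block `rho` must be in [0, 1).")
    list(size = size, rho = rho)
  })
  total_block <- sum(vapply(blocks, function(b) b$size, integer(1)))
  start <- if (blocks_informative) 0L else n_informative
  if (start + total_block > p) {
    stop_config("Correlated blocks do not fit into `p` features.")
  }
  if (!is.null(seed)) set.seed(seed)

  y <- stats::rbinom(n, 1L, balance)
  while (length(unique(y)) < 2L) {
    y <- stats::rbinom(n, 1L, balance)
  }
  x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  at <- start
  for (b in blocks) {
    f <- stats::rnorm(n)
    idx <- at + seq_len(b$size)
    x[, idx] <- sqrt(b$rho) * f + sqrt(1 - b$rho) * x[, idx]
    at <- at + b$size
  }
  if (n_informative > 0L) {
    shift <- ifelse(y == 1L, effect / 2, -effect / 2)
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
  }
  colnames(x) <- sprintf(paste0("f%0", max(3L, nchar(p)), "d"), seq_len(p))
  out <- tibble::as_tibble(as.data.frame(x))
  out$class <- factor(ifelse(y == 1L, "pos", "neg"), levels = c("neg", "pos"))
  out <- dplyr::relocate(out, "class")
  attr(out, "informative") <- seq_len(n_informative)
  attr(out, "spec") <- list(
    n = n, p = p, n_informative = n_informative, effect = effect,
    blocks = blocks, balance = balance, blocks_informative = blocks_informative,
    seed = seed
  )
  out
}

#' Random selection ensembles
#'
#' Draws `m` independent uniform `k`-subsets of `1:p` — the random-selection
#' null under which chance-corrected stability measures have constant
#' expectation regardless of `k`.
#'
#' @param m Number of sets (at least 2).
#' @param p Number of candidate features.
#' @param k Size of every set, `1 <= k <= p`.
#' @param seed Optional integer seed.
#' @return A [selection_ensemble()].
#' @examples
#' stability_correlation(random_selection_ensemble(10, 50, 5, seed = 1))
#' @export
random_selection_ensemble <- function(m, p, k, seed = NULL) {
  if (k < 1L || k > p) {
    stop_shape("`k` must be between 1 and `p`.")
  }
  if (!is.null(seed)) set.seed(seed)
  selection_ensemble(
    lapply(seq_len(m), function(i) sample.int(p, k)),
    p = p
  )
}
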