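#' Feature-selection stability measures
#'
#' Nine measures of how reproducible a feature selection is across the `m`
#' resampled feature sets of a [selection_ensemble()]. All measures are
#' oriented so that high values indicate high stability.
#'
#' The pairwise (intersection- and correlation-based) measures are means over
#' all \eqn{m(m-1)/2} unordered set pairs of a pairwise similarity:
#'
#' * `stability_jaccard()` (`SJ`): \eqn{|V_i \cap V_j| / |V_i \cup V_j|}.
#' * `stability_dice()` (`SD`): \eqn{2|V_i \cap V_j| / (|V_i| + |V_j|)}.
#' * `stability_ochiai()` (`SO`): \eqn{|V_i \cap V_j| / \sqrt{|V_i||V_j|}}.
#' * `stability_zucknick()` (`SZ`): the Jaccard similarity augmented with
#'   cross-set Pearson correlations, so that selecting different but highly
#'   correlated features (as happens with co-expressed gene blocks) still
#'   counts towards stability; see Details.
#' * `stability_lustgarten()` (`SL`): the intersection size centred by its
#'   expectation under random selection and scaled by its attainable range --
#'   a measure corrected for chance, in \eqn{[-1, 1]}.
#' * `stability_correlation()` (`SC`): the Pearson correlation of the binary
#'   indicator vectors \eqn{z_i, z_j \in \{0,1\}^p}, equivalently the phi
#'   coefficient of their 2x2 contingency table; corrected for chance.
#'
#' The frequency-based measures work with the selection counts
#' \eqn{h_j}:
#'
#' * `stability_novovicova()` (`SN`): the entropy-type statistic
#'   \eqn{\frac{1}{q \log_2 m} \sum_{j \in V} h_j \log_2 h_j}.
#' * `stability_davis()` (`SD-alpha`):
#'   \eqn{\max(0, \frac{1}{|V|}\sum_j h_j/m - \alpha\,\mathrm{median}(|V_i|)/p)},
#'   which rewards frequently chosen features and (for \eqn{\alpha > 0})
#'   penalises large models.
#' * `stability_somol()` (`SS`): the relative weighted consistency
#'   \eqn{(D - c_{\min})/(c_{\max} - c_{\min})} with
#'   \eqn{D = \sum_j (h_j/q)\,(h_j - 1)/(m - 1)} and correction terms that
#'   depend on \eqn{q} through integer remainders, making it corrected for
#'   chance.
#'
#' @details For `stability_zucknick()` the pairwise score is
#'   \eqn{(|V_i \cap V_j| + c_{ij} + d_{ij}) / |V_i \cup V_j|} where
#'   \eqn{c_{ij} = \frac{1}{|V_j|}\sum_{x \in V_i}\sum_{y \in V_j \setminus V_i}
#'   \mathrm{Cor}(x, y)\,I(\mathrm{Cor}(x, y) > r_{ij})} (and symmetrically
#'   \eqn{d_{ij}}), with \eqn{r_{ij}} the median correlation over distinct
#'   feature pairs in \eqn{V_i \cup V_j}. The threshold comparison is strict
#'   (`strict = TRUE`): the interval notation \eqn{(r_{ij}, \infty)} is read as
#'   an open interval. Consequently for \eqn{|V_i \cup V_j| = 2} the single
#'   cross correlation never exceeds its own median and the score reduces to
#'   Jaccard. Set `strict = FALSE` to use `>=`.
#'
#'   Degenerate inputs raise typed conditions rather than returning silent
#'   values: empty sets (`stabsel_error_empty_set`) for all measures;
#'   all-features sets (`stabsel_error_degenerate_selection`) for `SL`, `SS`
#'   and `SC`, which are undefined when every feature is selected; missing
#'   correlations among union features (`stabsel_error_undefined_correlation`)
#'   for `SZ`.
#'
#' @param ens A [selection_ensemble()].
#' @param cor A p x p feature correlation matrix from
#'   [feature_correlations()] (only `stability_zucknick()`).
#' @param alpha Non-negative size penalty of the Davis measure.
#' @param strict Logical: use a strict `>` comparison against the median
#'   correlation threshold (default) or `>=`.
#'
#' @return A single numeric stability value.
#' @seealso [stability_all()] for evaluating all measures at once,
#'   [stability_range()] for the theoretical ranges.
#' @examples
#' ens <- selection_ensemble(list(c(1, 2), c(1, 3)), p = 10)
#' stability_jaccard(ens) # 1/3
#' stability_dice(ens) # 1/2
#' stability_correlation(ens)
#' @name stability-measures
NULL

check_nonempty <- function(ens) {
  if (any(ens_sizes(ens) == 0L)) {
    stop_empty_set()
  }
}

# Mean over unordered pairs of fun(i, j), given the intersection matrix
# M = Z Z^T (M[i, j] = |V_i intersect V_j|, diagonal = set sizes).
pairwise_mean <- function(ens, pair_fun) {
  z <- ens_indicator(ens)
  m <- nrow(z)
  inter <- tcrossprod(z)
  sizes <- diag(inter)
  total <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      total <- total + pair_fun(inter[i, j], sizes[i], sizes[j], i, j)
    }
  }
  total / (m * (m - 1L) / 2L)
}

#' @rdname stability-measures
#' @export
stability_jaccard <- function(ens) {
  check_nonempty(ens)
  pairwise_mean(ens, function(int, si, sj, i, j) int / (si + sj - int))
}

#' @rdname stability-measures
#' @export
stability_dice <- function(ens) {
  check_nonempty(ens)
  pairwise_mean(ens, function(int, si, sj, i, j) 2 * int / (si + sj))
}

#' @rdname stability-measures
#' @export
stability_ochiai <- function(ens) {
  check_nonempty(ens)
  pairwise_mean(ens, function(int, si, sj, i, j) int / sqrt(si * sj))
}

#' @rdname stability-measures
#' @export
stability_zucknick <- function(ens, cor, strict = TRUE) {
  check_nonempty(ens)
  if (!is.matrix(cor) || nrow(cor) != ens$p || ncol(cor) != ens$p) {
    stop_shape("`cor` must be a p x p correlation matrix.")
  }
  un <- ens_union(ens)
  if (anyNA(cor[un, un, drop = FALSE])) {
    stop_undefined_correlation(paste(
      "Undefined correlations (constant features) among the selected",
      "features; the correlation-adjusted measure is not defined."
    ))
  }
  sets <- ens$sets
  pairwise_mean(ens, function(int, si, sj, i, j) {
    vi <- sets[[i]]
    vj <- sets[[j]]
    u <- union(vi, vj)
    if (length(u) < 2L) {
      # identical singleton sets: no distinct pairs, no adjustment possible
      return(int / (si + sj - int))
    }
    cu <- cor[u, u, drop = FALSE]
    r <- stats::median(cu[upper.tri(cu)])
    pass <- function(x) if (strict) x > r else x >= r
    cij <- 0
    only_j <- setdiff(vj, vi)
    if (length(only_j)) {
      cc <- cor[vi, only_j, drop = FALSE]
      cij <- sum(cc[pass(cc)]) / sj
    }
    dij <- 0
    only_i <- setdiff(vi, vj)
    if (length(only_i)) {
      cc <- cor[vj, only_i, drop = FALSE]
      dij <- sum(cc[pass(cc)]) / si
    }
    (int + cij + dij) / (si + sj - int)
  })
}

#' @rdname stability-measures
#' @export
stability_lustgarten <- function(ens) {
  check_nonempty(ens)
  p <- ens$p
  pairwise_mean(ens, function(int, si, sj, i, j) {
    denom <- min(si, sj) - max(0, si + sj - p)
    if (denom == 0) {
      stop_degenerate(paste0(
        "Pairwise denominator 0 for sets ", i, " and ", j,
        " (e.g. all features selected): measure not defined."
      ))
    }
    (int - si * sj / p) / denom
  })
}

#' @rdname stability-measures
#' @export
stability_novovicova <- function(ens) {
  check_nonempty(ens)
  h <- ens_counts(ens)
  h <- h[h > 0L]
  q <- sum(h)
  m <- length(ens)
  sum(h * log2(h)) / (q * log2(m))
}

#' @rdname stability-measures
#' @export
stability_davis <- function(ens, alpha = 1) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop_config("`alpha` must be a single non-negative number.")
  }
  check_nonempty(ens)
  h <- ens_counts(ens)
  nv <- sum(h > 0L)
  m <- length(ens)
  max(0, sum(h / m) / nv - alpha * stats::median(ens_sizes(ens)) / ens$p)
}

#' @rdname stability-measures
#' @export
stability_somol <- function(ens) {
  check_nonempty(ens)
  h <- ens_counts(ens)
  q <- sum(h)
  m <- length(ens)
  p <- ens$p
  d_stat <- sum((h[h > 0L] / q) * (h[h > 0L] - 1) / (m - 1))
  c_min <- (q^2 - p * (q - q %% p) - (q %% p)^2) / (p * q * (m - 1))
  c_max <- ((q %% m)^2 + q * (m - 1) - (q %% m) * m) / (q * (m - 1))
  if (isTRUE(all.equal(c_min, c_max, tolerance = 1e-12))) {
    stop_degenerate(
      "c_max equals c_min (e.g. all features selected in every set): relative weighted consistency not defined."
    )
  }
  (d_stat - c_min) / (c_max - c_min)
}

#' @rdname stability-measures
#' @export
stability_correlation <- function(ens) {
  sizes <- ens_sizes(ens)
  if (any(sizes == 0L)) {
    stop_empty_set()
  }
  if (any(sizes == ens$p)) {
    stop_degenerate(
      "Constant indicator vector (all features selected): Pearson correlation of the indicators not defined."
    )
  }
  p <- ens$p
  pairwise_mean(ens, function(int, si, sj, i, j) {
    # phi coefficient from the 2x2 table of the two indicator vectors
    (p * int - si * sj) / sqrt(si * (p - si) * sj * (p - sj))
  })
}

measure_registry <- function(alphas = c(0, 1, 2, 10)) {
  base <- list(
    SJ = function(ens, cor) stability_jaccard(ens),
    SD = function(ens, cor) stability_dice(ens),
    SO = function(ens, cor) stability_ochiai(ens),
    SZ = function(ens, cor) {
      if (is.null(cor)) {
        stop_undefined_correlation(
          "A feature correlation matrix is required for the correlation-adjusted measure."
        )
      }
      stability_zucknick(ens, cor)
    },
    SL = function(ens, cor) stability_lustgarten(ens),
    SN = function(ens, cor) stability_novovicova(ens),
    SS = function(ens, cor) stability_somol(ens),
    SC = function(ens, cor) stability_correlation(ens)
  )
  for (a in alphas) {
    base[[paste0("SD-", a)]] <- local({
      alpha <- a
      function(ens, cor) stability_davis(ens, alpha)
    })
  }
  base
}

#' Theoretical range of a stability measure
#'
#' @param measure Measure identifier: one of `"SJ"`, `"SD"`, `"SO"`, `"SZ"`,
#'   `"SL"`, `"SN"`, `"SS"`, `"SC"` or `"SD-<alpha>"`.
#' @param p,m Number of candidate features and number of sets (needed only for
#'   the Davis measure, whose upper bound is
#'   \eqn{\max(1 - \alpha/p,\; 1/(m(m-1)/2))}).
#' @return A numeric vector `c(lower, upper)`.
#' @export
stability_range <- function(measure, p = NULL, m = NULL) {
  if (grepl("^SD-", measure)) {
    alpha <- as.numeric(sub("^SD-", "", measure))
    if (is.null(p) || is.null(m)) {
      stop_config("`p` and `m` are required for the range of the Davis measure.")
    }
    return(c(0, max(1 - alpha / p, 1 / (m * (m - 1) / 2))))
  }
  switch(measure,
    SJ = , SD = , SO = , SZ = , SN = , SS = c(0, 1),
    SL = , SC = c(-1, 1),
    stop_config(sprintf("Unknown stability measure '%s'.", measure))
  )
}

#' Evaluate all stability measures on one ensemble
#'
#' Convenience dispatcher over all implemented stability measures. Measures
#' whose preconditions fail on the given ensemble (for example the corrected
#' measures when every feature is selected) are reported as undefined (`NA`)
#' with the condition message in `note`, never silently dropped.
#'
#' @param ens A [selection_ensemble()].
#' @param cor Optional p x p feature correlation matrix; required for the
#'   correlation-adjusted measure `SZ`, which is reported as undefined when
#'   absent.
#' @param alphas Numeric vector of penalties at which to evaluate the Davis
#'   measure (default `c(0, 1, 2, 10)`).
#' @param measures Optional character vector restricting which measures to
#'   evaluate (identifiers as in [stability_range()]).
#'
#' @return A tibble with columns `measure`, `value`, `lower`, `upper`, `note`.
#' @examples
#' ens <- random_selection_ensemble(m = 5, p = 20, k = 4, seed = 1)
#' stability_all(ens)
#' @export
stability_all <- function(ens, cor = NULL, alphas = c(0, 1, 2, 10),
                          measures = NULL) {
  reg <- measure_registry(alphas)
  if (!is.null(measures)) {
    unknown <- setdiff(measures, names(reg))
    if (length(unknown)) {
      stop_config(sprintf(
        "Unknown stability measures: %s.", paste(unknown, collapse = ", ")
      ))
    }
    reg <- reg[measures]
  }
  m <- length(ens)
  rows <- purrr::imap(reg, function(fn, id) {
    value <- NA_real_
    note <- NA_character_
    tryCatch(
      value <- fn(ens, cor),
      stabsel_error = function(e) note <<- conditionMessage(e)
    )
    rng <- stability_range(id, p = ens$p, m = m)
    tibble::tibble(
      measure = id, value = value, lower = rng[1], upper = rng[2], note = note
    )
  })
  dplyr::bind_rows(rows)
}
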