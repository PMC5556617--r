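#' Filter methods for feature scoring
#'
#' Univariate (and, for MRMR, greedy multivariate) filters that score every
#' feature of a labeled data set; the top-scoring features are then kept with
#' [select_top_k()]. All features must be metric.
#'
#' * `filter_variance()` scores each feature by its sample variance
#'   (denominator `n - 1`); no labels are used.
#' * `filter_auc()` scores each feature by `|0.5 - AUC|`, where `AUC` is the
#'   area under the ROC curve of the single-feature threshold rule
#'   \eqn{\hat Y = I(X_j > c)} over all cutoffs `c`, computed rank-based with
#'   midrank tie handling (the normalised Mann-Whitney statistic). A feature
#'   that separates the classes perfectly in either direction scores 0.5; an
#'   uninformative feature scores 0.
#' * `filter_mrmr()` performs greedy maximum-relevance-minimum-redundancy
#'   forward selection: relevance is the AUC filter score, redundancy of a
#'   candidate given the chosen set is the sum of absolute Pearson
#'   correlations with the chosen features, and each step picks the candidate
#'   maximising relevance/redundancy. The first feature is the
#'   relevance-maximal one (redundancy over an empty set is not defined);
#'   a candidate with redundancy exactly 0 has quotient `+Inf` and such
#'   candidates are ranked among themselves by relevance. All score ties are
#'   broken by lowest feature index, so selection is deterministic.
#'
#' @param data A data frame with numeric feature columns and (except for the
#'   variance filter) a binary label column.
#' @param label Name of the label column (default `"class"`); for
#'   `filter_variance()` it is only dropped if present.
#' @param k Number of features for MRMR to choose (default all `p`; the greedy
#'   order for `k` features is the length-`k` prefix of the order for `p`).
#'
#' @return A tibble of class `filter_scores` with columns `index`, `feature`,
#'   `score` and, for MRMR, `rank` (greedy pick order, `NA` for unchosen
#'   features) and `quotient` (the relevance/redundancy value at the pick; the
#'   first pick has quotient `Inf`). The filter identifier is kept in the
#'   `filter` attribute.
#' @examples
#' d <- simulate_dataset(n = 60, p = 12, n_informative = 2, blocks = list(), seed = 1)
#' filter_auc(d) |> select_top_k(3)
#' @name filters
NULL

new_filter_scores <- function(index, feature, score, filter, ...) {
  out <- tibble::tibble(index = index, feature = feature, score = score, ...)
  attr(out, "filter") <- filter
  class(out) <- c("filter_scores", class(out))
  out
}

#' @rdname filters
#' @export
filter_variance <- function(data, label = "class") {
  x <- feature_matrix(data, label)
  if (nrow(x) < 2L) {
    stop_shape("At least two observations are required for a variance.")
  }
  new_filter_scores(
    index = seq_len(ncol(x)),
    feature = colnames(x),
    score = unname(apply(x, 2, stats::var)),
    filter = "variance"
  )
}

# Midrank AUC of each column of x against binary y, as the normalised
# Mann-Whitney U statistic.
auc_scores <- function(x, y) {
  y <- as.integer(y) == 2L # second factor level is the "positive" class
  n1 <- sum(y)
  n0 <- sum(!y)
  unname(apply(x, 2, function(v) {
    r <- rank(v) # midranks
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }))
}

#' @rdname filters
#' @export
filter_auc <- function(data, label = "class") {
  x <- feature_matrix(data, label)
  y <- label_vector(data, label)
  new_filter_scores(
    index = seq_len(ncol(x)),
    feature = colnames(x),
    score = abs(0.5 - auc_scores(x, y)),
    filter = "auc"
  )
}

#' @rdname filters
#' @export
filter_mrmr <- function(data, label = "class", k = NULL) {
  x <- feature_matrix(data, label)
  y <- label_vector(data, label)
  p <- ncol(x)
  if (is.null(k)) k <- p
  if (k < 1L || k > p) {
    stop_shape("`k` must be between 1 and the number of features.")
  }
  relevance <- abs(0.5 - auc_scores(x, y))
  ord <- mrmr_order(x, relevance, k)
  rank <- rep(NA_integer_, p)
  rank[ord$order] <- seq_along(ord$order)
  quotient <- rep(NA_real_, p)
  quotient[ord$order] <- ord$quotient
  new_filter_scores(
    index = seq_len(p),
    feature = colnames(x),
    score = relevance,
    filter = "mrmr",
    rank = rank,
    quotient = quotient
  )
}

# Greedy MRMR order over the columns of x. Redundancy is accumulated
# incrementally: after each pick, every remaining candidate's redundancy grows
# by |cor(candidate, pick)|. Constant candidates are only an error when their
# correlation is actually consulted (i.e. from the second step on).
mrmr_order <- function(x, relevance, k) {
  p <- ncol(x)
  chosen <- integer(k)
  quot <- numeric(k)
  free <- rep(TRUE, p)
  # ties by lowest index: which.max already returns the first maximum
  chosen[1L] <- which.max(relevance)
  quot[1L] <- Inf
  free[chosen[1L]] <- FALSE
  if (k == 1L) {
    return(list(order = chosen, quotient = quot))
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  ss <- sqrt(colSums(xc^2))
  redundancy <- rep(0, p)
  for (step in 2L:k) {
    last <- chosen[step - 1L]
    if (ss[last] == 0) {
      stop_undefined_correlation(
        "A chosen feature is constant; its correlations are undefined."
      )
    }
    newcor <- abs(as.vector(crossprod(xc, xc[, last])) / (ss * ss[last]))
    if (anyNA(newcor[free])) {
      stop_undefined_correlation(
        "Constant candidate features have undefined correlations; remove zero-variance features first."
      )
    }
    redundancy <- redundancy + newcor
    q <- ifelse(redundancy == 0, Inf, relevance / redundancy)
    q[!free] <- -Inf
    best <- which(q == max(q))
    if (length(best) > 1L) {
      if (is.infinite(max(q))) {
        # zero-redundancy candidates: rank by relevance, then lowest index
        best <- best[order(-relevance[best], best)][1L]
      } else {
        best <- best[1L] # tie-break by lowest index
      }
    }
    chosen[step] <- best
    quot[step] <- q[best]
    free[best] <- FALSE
  }
  list(order = chosen, quotient = quot)
}

#' Select the top features from filter scores
#'
#' Keeps either the `k` highest-scoring features or all features whose score
#' exceeds `threshold`. For MRMR scores the greedy pick order (`rank` column)
#' is used instead of the raw relevance score, so `select_top_k(scores, k)`
#' returns the first `k` greedy picks. Ties are broken by lowest feature
#' index, making the selection deterministic and nested in `k`.
#'
#' @param scores A `filter_scores` tibble from one of the [filters].
#' @param k Number of features to keep.
#' @param threshold Alternative to `k`: keep features with `score > threshold`.
#' @return A sorted integer vector of selected feature indices.
#' @export
select_top_k <- function(scores, k = NULL, threshold = NULL) {
  if (is.null(k) == is.null(threshold)) {
    stop_config("Provide exactly one of `k` and `threshold`.")
  }
  p <- nrow(scores)
  if (!is.null(threshold)) {
    return(scores$index[scores$score > threshold])
  }
  if (k < 1L || k > p) {
    stop_shape("`k` must be between 1 and the number of scored features.")
  }
  if (identical(attr(scores, "filter"), "mrmr")) {
    if (!"rank" %in% names(scores) || sum(!is.na(scores$rank)) < k) {
      stop_config("MRMR was run with fewer than `k` greedy steps; rerun filter_mrmr() with a larger `k`.")
    }
    return(sort(scores$index[!is.na(scores$rank) & scores$rank <= k]))
  }
  ord <- order(-scores$score, scores$index)
  sort(scores$index[ord[seq_len(k)]])
}
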