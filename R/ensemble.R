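#' Create a selection ensemble
#'
#' A selection ensemble holds the `m` feature sets \eqn{V_1, \dots, V_m}
#' obtained by running one feature-selection method on `m` resampled versions
#' of a data set (for example the ten training folds of a 10-fold
#' cross-validation). It is the input object of every stability measure.
#'
#' @param sets A list of `m >= 2` vectors, each the feature set selected on one
#'   resample. Sets may be given as integer indices in `1:p` or as character
#'   names (then `features` is required). Duplicate entries within a set are an
#'   error: the \eqn{V_i} are sets.
#' @param p Total number of candidate features.
#' @param features Optional character vector of the `p` feature names, used to
#'   resolve character sets and for printing.
#'
#' @return An object of class `selection_ensemble`: a list with elements
#'   `sets` (list of sorted integer vectors), `p` and `features`.
#'
#' @details Empty sets are allowed in the container (so that degenerate runs of
#'   a selector can be represented and reported); the individual stability
#'   measures reject them with a typed `stabsel_error_empty_set` condition.
#'
#' @examples
#' ens <- selection_ensemble(list(c(1, 2), c(1, 3)), p = 10)
#' stability_jaccard(ens)
#' @export
selection_ensemble <- function(sets, p, features = NULL) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop_shape("`sets` must be a list of at least two feature sets (m >= 2).")
  }
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L) {
    stop_shape("`p` must be a single positive integer.")
  }
  if (!is.null(features)) {
    features <- as.character(features)
    if (length(features) != p || anyDuplicated(features)) {
      stop_shape("`features` must be `p` unique names.")
    }
  }
  sets <- lapply(seq_along(sets), function(i) {
    v <- sets[[i]]
    if (is.character(v)) {
      if (is.null(features)) {
        stop_shape("Character feature sets require `features`.")
      }
      idx <- match(v, features)
      if (anyNA(idx)) {
        stop_shape(sprintf("Set %d contains unknown feature names.", i))
      }
      v <- idx
    }
    v <- as.integer(v)
    if (anyNA(v) || any(v < 1L) || any(v > p)) {
      stop_shape(sprintf("Set %d has indices outside 1..p.", i))
    }
    if (anyDuplicated(v)) {
      stop_shape(sprintf("Set %d contains duplicate features.", i))
    }
    sort(v)
  })
  structure(
    list(sets = sets, p = p, features = features),
    class = "selection_ensemble"
  )
}

#' @export
print.selection_ensemble <- function(x, ...) {
  sz <- ens_sizes(x)
  cat(sprintf(
    "<selection_ensemble> m = %d sets over p = %d features\n", length(x$sets), x$p
  ))
  cat(sprintf(
    "  |V_i|: %s\n  union size %d, q = %d\n",
    paste(sz, collapse = ", "), length(ens_union(x)), sum(sz)
  ))
  invisible(x)
}

#' @export
length.selection_ensemble <- function(x) length(x$sets)

#' Ensemble summaries
#'
#' Accessors for the derived quantities of a [selection_ensemble()]:
#' cardinalities \eqn{|V_i|}, per-feature selection counts
#' \eqn{h_j = \#\{i : j \in V_i\}}, total count \eqn{q = \sum_j h_j}, the
#' union \eqn{V = \cup_i V_i} and the m x p binary indicator matrix whose rows
#' are the vectors \eqn{z_i}.
#'
#' @param ens A [selection_ensemble()].
#' @return `ens_sizes()` an integer vector of length `m`; `ens_counts()` an
#'   integer vector of length `p`; `ens_union()` the sorted indices in the
#'   union; `ens_indicator()` an m x p 0/1 matrix.
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
ens_sizes <- function(ens) {
  vapply(ens$sets, length, integer(1))
}

#' @rdname ensemble-accessors
#' @export
ens_counts <- function(ens) {
  tabulate(unlist(ens$sets), nbins = ens$p)
}

#' @rdname ensemble-accessors
#' @export
ens_union <- function(ens) {
  sort(unique(unlist(ens$sets)))
}

#' @rdname ensemble-accessors
#' @export
ens_indicator <- function(ens) {
  m <- length(ens$sets)
  z <- matrix(0L, nrow = m, ncol = ens$p)
  for (i in seq_len(m)) {
    z[i, ens$sets[[i]]] <- 1L
  }
  z
}

#' Tidy a selection ensemble
#'
#' @param x A [selection_ensemble()].
#' @param ... Unused.
#' @return A tibble with one row per (set, feature) pair: `set`, `index` and
#'   (when names are known) `feature`.
#' @export
tidy.selection_ensemble <- function(x, ...) {
  out <- tibble::tibble(
    set = rep.int(seq_along(x$sets), lengths(x$sets)),
    index = unlist(x$sets, use.names = FALSE)
  )
  if (!is.null(x$features)) {
    out$feature <- x$features[out$index]
  }
  out
}
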