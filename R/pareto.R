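#' Pareto dominance
#'
#' A criteria vector `y` Pareto-dominates `z` (both minimisation-oriented) if
#' it is no worse in every component and strictly better in at least one.
#'
#' @param y,z Numeric criteria vectors of equal length, all entries finite.
#' @return `TRUE` or `FALSE`.
#' @examples
#' dominates(c(1, 2), c(2, 2)) # TRUE
#' dominates(c(1, 3), c(2, 1)) # FALSE (incomparable)
#' @export
dominates <- function(y, z) {
  if (length(y) != length(z)) {
    stop_shape("Criteria vectors must have equal length.")
  }
  if (!all(is.finite(y)) || !all(is.finite(z))) {
    stop_shape("Criteria vectors must be finite.")
  }
  all(y <= z) && any(y < z)
}

#' Pareto front of a set of points
#'
#' Extracts the rows whose criteria vectors are not dominated by any other
#' row. All criteria are minimised. Duplicates of a nondominated vector are
#' all retained, so distinct configurations with identical criteria keep
#' their provenance.
#'
#' @param points A data frame of points.
#' @param ... Tidy-selection of the criteria columns (default: all numeric
#'   columns).
#' @return The subset of `points` forming the front, in input order.
#' @examples
#' pts <- tibble::tibble(a = c(1, 2, 3, 2), b = c(3, 2, 1, 3))
#' pareto_front(pts) # drops (2, 3)
#' @export
pareto_front <- function(points, ...) {
  if (!is.data.frame(points) || nrow(points) == 0L) {
    stop_shape("`points` must be a data frame with at least one row.")
  }
  sel <- rlang::enquos(...)
  crit <- if (length(sel)) {
    dplyr::select(points, !!!sel)
  } else {
    dplyr::select(points, dplyr::where(is.numeric))
  }
  mat <- as.matrix(crit)
  if (ncol(mat) < 1L) {
    stop_shape("At least one numeric criteria column is required.")
  }
  if (any(!is.finite(mat))) {
    stop_shape("Criteria must be finite to assess dominance.")
  }
  points[!dominated_rows(mat), , drop = FALSE]
}

# O(n^2) pairwise scan; row i is dominated if some j is <= everywhere and <
# somewhere.
dominated_rows <- function(mat) {
  n <- nrow(mat)
  out <- logical(n)
  for (i in seq_len(n)) {
    le <- rep(TRUE, n)
    lt <- rep(FALSE, n)
    for (k in seq_len(ncol(mat))) {
      le <- le & (mat[, k] <= mat[i, k])
      lt <- lt | (mat[, k] < mat[i, k])
    }
    out[i] <- any(le & lt)
  }
  out
}

#' Accuracy band around the best configuration
#'
#' Retains the configurations whose mean misclassification rate does not
#' exceed \eqn{c^* + \delta}, where \eqn{c^*} is the best (smallest) mean
#' misclassification rate achieved by any configuration in `results`.
#' Accuracy is treated as the primary criterion: the subsequent
#' stability/size Pareto analysis is restricted to this band.
#'
#' @param results A results tibble (from [tidy()] on a [random_search()]
#'   object, or the object itself) with an `error` column. Rows with `NA`
#'   error (failed configurations) are ignored.
#' @param delta Band width above `c_star` (default 0.05).
#' @return The retained rows, with attributes `c_star` and `delta`.
#' @export
accuracy_band <- function(results, delta = 0.05) {
  results <- as_results(results)
  ok <- !is.na(results$error)
  if (!any(ok)) {
    stop_shape("No configuration with a defined error.")
  }
  c_star <- min(results$error[ok])
  out <- results[ok & results$error <= c_star + delta, , drop = FALSE]
  attr(out, "c_star") <- c_star
  attr(out, "delta") <- delta
  out
}

as_results <- function(results) {
  if (inherits(results, "stab_search")) {
    return(results$results)
  }
  if (!is.data.frame(results)) {
    stop_shape("`results` must be a stab_search object or a results tibble.")
  }
  if (!"error" %in% names(results)) {
    stop_shape("`results` must contain an `error` column.")
  }
  results
}

#' Desirable configurations: stability/size Pareto fronts
#'
#' Implements the accuracy-band multicriteria selection: transform the chosen
#' stability measure into `1 - stability` so that all criteria are minimised,
#' then extract Pareto-optimal configurations.
#'
#' Two modes:
#' * `"band2d"` (default): keep only configurations whose error is within
#'   `delta` of the best error ([accuracy_band()]), then take the Pareto
#'   front over (`1 - stability`, `size`).
#' * `"3d"`: no band; Pareto front over (`error`, `1 - stability`, `size`).
#'
#' Configurations for which the chosen measure is undefined (degenerate
#' ensembles) are excluded from the analysis with a warning, never silently
#' treated as 0.
#'
#' @inheritParams accuracy_band
#' @param measure Stability measure column to use (e.g. `"SC"`, `"SJ"`,
#'   `"SD-1"`).
#' @param mode `"band2d"` or `"3d"`.
#' @return The front rows, with an added `instability` column
#'   (`1 - stability`) and attributes `measure`, `mode` and (for `"band2d"`)
#'   `c_star`, `delta`.
#' @examples
#' \donttest{
#' d <- simulate_dataset(n = 60, p = 30, seed = 1)
#' sr <- random_search(d, n_configs = 12, folds = 5, seed = 1)
#' desirable_configurations(sr, measure = "SC")
#' }
#' @export
desirable_configurations <- function(results, measure = "SC", delta = 0.05,
                                     mode = c("band2d", "3d")) {
  mode <- match.arg(mode)
  results <- as_results(results)
  if (!measure %in% names(results)) {
    stop_config(sprintf("No column '%s' in the results.", measure))
  }
  undef <- is.na(results[[measure]]) & !is.na(results$error)
  if (any(undef)) {
    warning(sprintf(
      "%d configuration(s) have an undefined %s value and are excluded from the front.",
      sum(undef), measure
    ), call. = FALSE)
  }
  results <- results[!is.na(results[[measure]]) & !is.na(results$error), ,
    drop = FALSE
  ]
  if (nrow(results) == 0L) {
    stop_shape(sprintf("No configuration with a defined '%s' value.", measure))
  }
  c_star <- NULL
  if (mode == "band2d") {
    results <- accuracy_band(results, delta)
    c_star <- attr(results, "c_star")
  }
  results$instability <- 1 - results[[measure]]
  front <- if (mode == "band2d") {
    pareto_front(results, "instability", "size")
  } else {
    pareto_front(results, "error", "instability", "size")
  }
  attr(front, "measure") <- measure
  attr(front, "mode") <- mode
  if (!is.null(c_star)) {
    attr(front, "c_star") <- c_star
    attr(front, "delta") <- delta
  }
  front
}
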