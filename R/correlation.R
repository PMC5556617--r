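#' Pairwise Pearson correlations between features
#'
#' Computes the p x p matrix of Pearson correlations between all feature
#' columns of a labeled data frame. Constant (zero-variance) features have no
#' defined correlation; their rows/columns are stored as `NA` rather than an
#' arbitrary number, and downstream consumers (the correlation-adjusted
#' stability measure, MRMR redundancy) reject them explicitly when they are
#' actually needed.
#'
#' @param data A data frame of observations x features, optionally containing
#'   the class-label column.
#' @param label Name of the label column to drop before computing correlations
#'   (ignored if absent).
#' @return A symmetric p x p numeric matrix with unit diagonal and `NA` for
#'   undefined entries, with feature names as dimnames.
#' @examples
#' d <- simulate_dataset(n = 50, p = 8, blocks = list(), seed = 1)
#' cc <- feature_correlations(d)
#' range(cc[upper.tri(cc)])
#' @export
feature_correlations <- function(data, label = "class") {
  x <- feature_matrix(data, label)
  cc <- suppressWarnings(stats::cor(x))
  # cor() leaves NaN for zero-variance columns; normalise to NA and force the
  # diagonal of non-constant features to exactly 1
  cc[!is.finite(cc)] <- NA_real_
  v <- apply(x, 2, stats::var)
  const <- !is.finite(v) | v == 0
  diag(cc) <- ifelse(const, NA_real_, 1)
  cc
}

# Extract the numeric feature matrix (drops the label column if present).
feature_matrix <- function(data, label = "class") {
  if (!is.data.frame(data)) {
    stop_shape("`data` must be a data frame.")
  }
  feats <- setdiff(names(data), label)
  x <- data[feats]
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad)) {
    stop_format(sprintf(
      "All feature columns must be numeric; offending: %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  as.matrix(x)
}

# Extract and validate the binary label as a factor with two levels.
label_vector <- function(data, label = "class") {
  if (!label %in% names(data)) {
    stop_format(sprintf("Label column '%s' not found.", label))
  }
  y <- factor(data[[label]])
  if (anyNA(data[[label]])) {
    stop_format(sprintf("Label column '%s' contains missing values.", label))
  }
  if (nlevels(y) != 2L) {
    if (nlevels(y) < 2L) stop_single_class()
    stop_format(sprintf(
      "Label column '%s' must have exactly two classes, found %d.",
      label, nlevels(y)
    ))
  }
  y
}
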