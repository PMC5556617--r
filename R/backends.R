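#' Classifier backends
#'
#' The evaluation engine treats classifiers as pluggable backends behind a
#' small contract: fit on a training matrix, score a test matrix with a
#' positive-class probability (classified at 0.5), and report which features
#' the fitted model actually uses. Four families are provided:
#'
#' * `"glmboost"` — componentwise gradient boosting for the logistic loss with
#'   linear base learners (hyperparameter `m_stop`, the number of boosting
#'   iterations). A feature is used iff its base learner is picked in at least
#'   one iteration, so small `m_stop` gives sparse models.
#' * `"lasso"` — L1-penalised logistic regression via \pkg{glmnet}
#'   (hyperparameter `lambda`). Used features are those with nonzero
#'   regression coefficients.
#' * `"rf"` — a bootstrap/Gini random forest (hyperparameters `num_trees`,
#'   `min_node_size`, with `mtry = floor(sqrt(p))`). Used features are those
#'   with impurity importance strictly greater than 0.
#' * `"svm"` — a radial-basis-kernel classifier (hyperparameters `sigma`,
#'   `C`), fitted by kernel ridge regression on the +/-1 class coding with
#'   penalty `1/C` and kernel \eqn{k(x, x') = \exp(-\sigma \|x - x'\|^2)}. No
#'   embedded selection: the model always uses all supplied features.
#'
#' `list_backends()` returns the available identifiers. `get_backend()`
#' returns the backend definition: a list with elements `params` (names of
#' accepted hyperparameters) and `fit(x, y, params, xtest)`, which returns
#' `selected` (integer indices into the columns of `x`) and `prob`
#' (positive-class probabilities for `xtest`).
#'
#' @name backends
NULL

#' @rdname backends
#' @export
list_backends <- function() names(backend_registry)

#' @rdname backends
#' @param name Backend identifier.
#' @export
get_backend <- function(name) {
  if (!name %in% names(backend_registry)) {
    stop_config(sprintf(
      "Unknown classifier '%s'; available: %s.",
      name, paste(list_backends(), collapse = ", ")
    ))
  }
  backend_registry[[name]]
}

fit_glmboost <- function(x, y, params, xtest) {
  m_stop <- as.integer(params$m_stop)
  fit <- .cw_boost(x, as.integer(y) - 1L, m_stop, 0.1)
  prob <- if (nrow(xtest)) {
    stats::plogis(fit$intercept + as.vector(xtest %*% fit$beta))
  } else {
    numeric(0)
  }
  list(selected = which(fit$used), prob = prob, model = fit)
}

fit_lasso <- function(x, y, params, xtest) {
  # glmnet needs >= 2 columns; pad with an all-zero column (coefficient 0)
  padded <- ncol(x) < 2L
  if (padded) {
    x <- cbind(x, 0)
    xtest <- cbind(xtest, 0)
  }
  fit <- glmnet::glmnet(
    x, y,
    family = "binomial", lambda = params$lambda, standardize = TRUE
  )
  beta <- as.vector(fit$beta)
  selected <- which(beta != 0)
  if (padded) selected <- selected[selected <= 1L]
  prob <- if (nrow(xtest)) {
    as.vector(stats::predict(fit, newx = xtest, type = "response"))
  } else {
    numeric(0)
  }
  list(selected = selected, prob = prob, model = fit)
}

fit_rf <- function(x, y, params, xtest) {
  fit <- .forest_fit_predict(
    x, as.integer(y) - 1L, xtest,
    as.integer(params$num_trees),
    max(1L, floor(sqrt(ncol(x)))),
    as.integer(params$min_node_size)
  )
  list(selected = which(fit$importance > 0), prob = fit$votes, model = fit)
}

fit_svm <- function(x, y, params, xtest) {
  sigma <- params$sigma
  cost <- params$C
  target <- ifelse(as.integer(y) == 2L, 1, -1)
  k <- exp(-sigma * sqdist(x, x))
  alpha <- solve(k + diag(1 / cost, nrow(x)), target)
  prob <- if (nrow(xtest)) {
    d <- as.vector(exp(-sigma * sqdist(xtest, x)) %*% alpha)
    pmin(pmax((d + 1) / 2, 0), 1) # decision value 0 maps to probability 0.5
  } else {
    numeric(0)
  }
  list(selected = seq_len(ncol(x)), prob = prob, model = list(alpha = alpha))
}

# squared Euclidean distances between the rows of a and the rows of b
sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

backend_registry <- list(
  glmboost = list(params = "m_stop", fit = fit_glmboost),
  lasso = list(params = "lambda", fit = fit_lasso),
  rf = list(params = c("num_trees", "min_node_size"), fit = fit_rf),
  svm = list(params = c("sigma", "C"), fit = fit_svm)
)
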