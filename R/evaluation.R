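#' Define a filter + classifier configuration
#'
#' A configuration is one "augmented method" with fixed hyperparameter values:
#' a filter method that keeps `n_feats` features, followed by a classifier
#' whose embedded feature selection may reduce the set further. The admissible
#' hyperparameter ranges are `m_stop`, `num_trees` in `{1..2^15}`,
#' `min_node_size` in `{1..2^5}` and `lambda`, `sigma`, `C` in
#' `[2^-15, 2^15]`; `n_feats` must be between 1 and the number of features of
#' the data the configuration is evaluated on (checked at evaluation time).
#'
#' @param filter One of `"variance"`, `"auc"`, `"mrmr"`, `"none"`.
#' @param n_feats Number of features the filter keeps (ignored for `"none"`).
#' @param classifier One of [list_backends()].
#' @param ... Hyperparameters of the chosen classifier (see [backends]).
#' @return A list of class `stab_config`.
#' @examples
#' configuration("auc", n_feats = 10, classifier = "lasso", lambda = 0.1)
#' @export
configuration <- function(filter = c("variance", "auc", "mrmr", "none"),
                          n_feats = NULL, classifier, ...) {
  filter <- match.arg(filter)
  backend <- get_backend(classifier)
  params <- list(...)
  missing <- setdiff(backend$params, names(params))
  extra <- setdiff(names(params), backend$params)
  if (length(missing) || length(extra)) {
    stop_config(sprintf(
      "Classifier '%s' takes hyperparameters {%s}; missing: {%s}, unknown: {%s}.",
      classifier, paste(backend$params, collapse = ", "),
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ))
  }
  check_range <- function(nm, value, lo, hi, int = FALSE) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value < lo || value > hi || (int && value != round(value))) {
      stop_config(sprintf(
        "Hyperparameter %s = %s outside its admissible range [%s, %s]%s.",
        nm, format(value), format(lo), format(hi),
        if (int) " (integer)" else ""
      ))
    }
  }
  for (nm in names(params)) {
    switch(nm,
      m_stop = , num_trees = check_range(nm, params[[nm]], 1, 2^15, int = TRUE),
      min_node_size = check_range(nm, params[[nm]], 1, 2^5, int = TRUE),
      lambda = , sigma = , C = check_range(nm, params[[nm]], 2^-15, 2^15)
    )
  }
  if (filter != "none") {
    if (is.null(n_feats) || n_feats < 1 || n_feats != round(n_feats)) {
      stop_config("`n_feats` must be a positive integer when a filter is used.")
    }
    n_feats <- as.integer(n_feats)
  } else {
    n_feats <- NA_integer_
  }
  structure(
    list(
      filter = filter, n_feats = n_feats, classifier = classifier,
      params = params
    ),
    class = "stab_config"
  )
}

#' @export
print.stab_config <- function(x, ...) {
  pp <- paste(names(x$params), vapply(x$params, format, character(1)),
    sep = " = ", collapse = ", "
  )
  cat(sprintf(
    "<stab_config> %s filter (n_feats = %s) + %s (%s)\n",
    x$filter, x$n_feats, x$classifier, pp
  ))
  invisible(x)
}

#' Default configuration space
#'
#' The random-search space: every combination of the three filters with the
#' four classifier families (12 augmented methods), `n_feats` uniform on
#' `{1..p}`, `m_stop` and `num_trees` uniform on `{1..2^15}`, `min_node_size`
#' uniform on `{1..2^5}`, and `lambda`, `sigma`, `C` drawn as `2^x` with `x`
#' uniform on `[-15, 15]`.
#'
#' @param p Number of features of the data set to be searched on.
#' @return A list describing the space, consumed by [sample_configurations()].
#' @export
config_space <- function(p) {
  list(
    filters = c("variance", "auc", "mrmr"),
    classifiers = list_backends(),
    n_feats = list(type = "int", min = 1L, max = as.integer(p)),
    params = list(
      m_stop = list(type = "int", min = 1L, max = 2L^15L),
      num_trees = list(type = "int", min = 1L, max = 2L^15L),
      min_node_size = list(type = "int", min = 1L, max = 2L^5L),
      lambda = list(type = "log2", min = -15, max = 15),
      sigma = list(type = "log2", min = -15, max = 15),
      C = list(type = "log2", min = -15, max = 15)
    )
  )
}

draw_param <- function(spec) {
  switch(spec$type,
    int = sample(seq.int(spec$min, spec$max), 1L),
    log2 = 2^stats::runif(1L, spec$min, spec$max),
    stop_config(sprintf("Unknown parameter type '%s'.", spec$type))
  )
}

#' Sample random configurations
#'
#' Draws hyperparameter configurations independently and uniformly from a
#' configuration space, either `n` per augmented method (filter x classifier
#' combination) or `n` in total, allocated to the augmented methods as evenly
#' as possible in a fixed cyclic order.
#'
#' @param space A space from [config_space()] (or the same shape read from
#'   YAML/JSON).
#' @param n Number of configurations.
#' @param per_method If `TRUE`, `n` configurations are drawn for every
#'   augmented method; if `FALSE` (default), `n` is the total.
#' @param seed Optional integer seed.
#' @return A tibble with one row per configuration: `config_id`, `filter`,
#'   `n_feats`, `classifier` and one column per hyperparameter (`NA` where a
#'   parameter does not apply to the classifier).
#' @export
sample_configurations <- function(space, n, per_method = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  methods <- tidyr::expand_grid(
    filter = space$filters, classifier = space$classifiers
  )
  n_methods <- nrow(methods)
  counts <- if (per_method) {
    rep(n, n_methods)
  } else {
    base <- n %/% n_methods
    rep(base, n_methods) + (seq_len(n_methods) <= n %% n_methods)
  }
  param_names <- names(space$params)
  rows <- list()
  for (mi in seq_len(n_methods)) {
    cls <- methods$classifier[mi]
    needed <- get_backend(cls)$params
    for (r in seq_len(counts[mi])) {
      row <- c(
        list(
          filter = methods$filter[mi],
          n_feats = as.integer(draw_param(space$n_feats)),
          classifier = cls
        ),
        stats::setNames(
          lapply(param_names, function(nm) {
            if (nm %in% needed) draw_param(space$params[[nm]]) else NA_real_
          }),
          param_names
        )
      )
      rows[[length(rows) + 1L]] <- tibble::as_tibble(row)
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, config_id = dplyr::row_number(), .before = 1L)
}

config_from_row <- function(row) {
  needed <- get_backend(row$classifier)$params
  params <- as.list(row)[needed]
  do.call(configuration, c(
    list(
      filter = row$filter, n_feats = row$n_feats, classifier = row$classifier
    ),
    params
  ))
}

#' Stratified cross-validation splits
#'
#' Partitions `1:length(y)` into `folds` disjoint test blocks whose sizes
#' differ by at most one, stratified by class so that every fold preserves the
#' class balance as far as integer counts allow.
#'
#' @param y The class label vector (its length defines `n`).
#' @param folds Number of folds (default 10, at least 2).
#' @param seed Optional integer seed; identical seeds give identical splits.
#' @return A list of `folds` elements, each `list(train = <row indices>,
#'   test = <row indices>)`.
#' @export
cv_splits <- function(y, folds = 10, seed = NULL) {
  n <- length(y)
  if (folds < 2L || n < folds) {
    stop_shape("`folds` must be at least 2 and at most the number of rows.")
  }
  if (!is.null(seed)) set.seed(seed)
  y <- factor(y)
  fold_of <- integer(n)
  offset <- 0L
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
    offset <- (offset + length(idx)) %% folds
  }
  lapply(seq_len(folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Fit one configuration and extract its feature set
#'
#' Applies the configuration's filter to the training data, fits the
#' classifier backend on the reduced matrix and returns the set of features
#' actually used by the final model — the cascade of the filter selection and
#' the classifier's embedded selection. When `newdata` is supplied the
#' held-out observations are scored in the same call.
#'
#' @param train A data frame of training observations (features + label).
#' @param config A [configuration()].
#' @param label Name of the label column.
#' @param newdata Optional data frame of observations to predict.
#' @return A list with `selected` (integer indices into the full feature set),
#'   `filtered` (indices kept by the filter), `levels` (class levels) and,
#'   when `newdata` is given, `prob` (positive-class probabilities) and
#'   `pred` (factor predictions at the 0.5 threshold).
#' @export
fit_and_extract <- function(train, config, label = "class", newdata = NULL) {
  x <- feature_matrix(train, label)
  y <- label_vector(train, label)
  p <- ncol(x)
  keep <- seq_len(p)
  if (config$filter != "none") {
    if (config$n_feats > p) {
      stop_config(sprintf(
        "`n_feats` = %d exceeds the %d available features.", config$n_feats, p
      ))
    }
    scores <- switch(config$filter,
      variance = filter_variance(train, label),
      auc = filter_auc(train, label),
      mrmr = filter_mrmr(train, label, k = config$n_feats)
    )
    keep <- select_top_k(scores, k = config$n_feats)
  }
  xtest <- if (is.null(newdata)) {
    matrix(0, nrow = 0L, ncol = length(keep))
  } else {
    feature_matrix(newdata, label)[, keep, drop = FALSE]
  }
  backend <- get_backend(config$classifier)
  fit <- tryCatch(
    backend$fit(x[, keep, drop = FALSE], y, config$params, xtest),
    error = function(e) {
      if (inherits(e, "stabsel_error")) rlang::cnd_signal(e)
      stop_backend(sprintf(
        "Classifier backend '%s' failed: %s", config$classifier,
        conditionMessage(e)
      ))
    }
  )
  out <- list(
    selected = keep[fit$selected],
    filtered = keep,
    levels = levels(y),
    model = fit$model
  )
  if (!is.null(newdata)) {
    out$prob <- fit$prob
    out$pred <- factor(
      ifelse(fit$prob > 0.5, levels(y)[2L], levels(y)[1L]),
      levels = levels(y)
    )
  }
  out
}

#' Cross-validated evaluation of one configuration
#'
#' Evaluates a configuration by stratified `folds`-fold cross-validation: on
#' each training part the filter is fitted and the classifier trained, the
#' held-out part is predicted, and the per-fold misclassification rate and
#' used feature set are recorded. The three criteria of interest are the mean
#' misclassification rate (`error`), the mean number of used features
#' (`size`), and the stability of the `folds` feature sets under every
#' requested stability measure.
#'
#' The correlation context for the correlation-adjusted stability measure is
#' computed once from the full data matrix, so all fold pairs share one
#' correlation notion (set `cor` explicitly to override).
#'
#' @param data A labeled data frame.
#' @param config A [configuration()].
#' @param label Name of the label column.
#' @param folds Number of CV folds (default 10).
#' @param measures Stability measures to evaluate (default: all, with the
#'   Davis measure at each of `alphas`).
#' @param alphas Davis penalty values (default `c(0, 1, 2, 10)`).
#' @param seed Optional integer seed for the fold assignment (and any
#'   stochastic backend).
#' @param cor Optional precomputed feature correlation matrix.
#' @return An object of class `stab_eval` with elements `config`, `error`,
#'   `size`, `fold_errors`, `ensemble` (a [selection_ensemble()]),
#'   `stability` (tibble from [stability_all()]), `folds`, `seed`.
#'   [tidy()] returns the stability tibble, [glance()] a one-row summary.
#' @examples
#' \donttest{
#' d <- simulate_dataset(n = 60, p = 30, n_informative = 2, seed = 7)
#' cfg <- configuration("auc", 5, classifier = "lasso", lambda = 0.05)
#' ev <- evaluate_configuration(d, cfg, folds = 5, seed = 1)
#' glance(ev)
#' }
#' @export
evaluate_configuration <- function(data, config, label = "class", folds = 10,
                                   measures = NULL, alphas = c(0, 1, 2, 10),
                                   seed = NULL, cor = NULL) {
  y <- label_vector(data, label)
  p <- ncol(data) - 1L
  splits <- cv_splits(y, folds, seed)
  if (needs_cor(measures) && is.null(cor)) {
    cor <- feature_correlations(data, label)
  }
  fold_errors <- numeric(folds)
  sets <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- data[splits[[f]]$train, , drop = FALSE]
    te <- data[splits[[f]]$test, , drop = FALSE]
    fit <- tryCatch(
      fit_and_extract(tr, config, label, newdata = te),
      error = function(e) {
        stop_backend(sprintf("Fold %d: %s", f, conditionMessage(e)))
      }
    )
    fold_errors[f] <- mean(fit$pred != te[[label]])
    sets[[f]] <- fit$selected
  }
  ens <- selection_ensemble(sets, p = p, features = setdiff(names(data), label))
  new_stab_eval(config, fold_errors, ens, cor, measures, alphas, folds, seed)
}

needs_cor <- function(measures) is.null(measures) || "SZ" %in% measures

new_stab_eval <- function(config, fold_errors, ens, cor, measures, alphas,
                          folds, seed) {
  structure(
    list(
      config = config,
      error = mean(fold_errors),
      size = mean(ens_sizes(ens)),
      fold_errors = fold_errors,
      ensemble = ens,
      stability = stability_all(ens, cor, alphas = alphas, measures = measures),
      folds = folds,
      seed = seed
    ),
    class = "stab_eval"
  )
}

#' @export
print.stab_eval <- function(x, ...) {
  cat(sprintf(
    "<stab_eval> %d-fold CV: error %.4f, mean size %.1f\n",
    x$folds, x$error, x$size
  ))
  print(x$stability)
  invisible(x)
}

#' @rdname evaluate_configuration
#' @param x A `stab_eval` object.
#' @param ... Unused.
#' @export
tidy.stab_eval <- function(x, ...) x$stability

#' @rdname evaluate_configuration
#' @export
glance.stab_eval <- function(x, ...) {
  tibble::tibble(
    error = x$error, size = x$size, folds = x$folds,
    p = x$ensemble$p, filter = x$config$filter,
    n_feats = x$config$n_feats, classifier = x$config$classifier
  )
}

#' Random hyperparameter search over augmented methods
#'
#' Samples configurations from a configuration space (by default the
#' [config_space()] of the data), evaluates each by `folds`-fold
#' cross-validation against the three criteria — mean misclassification rate,
#' mean number of used features, and feature-selection stability — and
#' returns everything as one tidy table. All configurations share a single
#' stratified CV split (derived from `seed`), which makes their criteria
#' directly comparable and lets filter rankings be computed once per
#' (fold, filter-method) pair and reused across configurations.
#'
#' Individual configuration failures (a backend error on one fold, say) are
#' recorded in the `note` column of the result, with `NA` criteria; they never
#' abort the sweep.
#'
#' @inheritParams evaluate_configuration
#' @param n_configs Number of configurations to draw.
#' @param per_method If `TRUE`, draw `n_configs` per augmented method (12
#'   methods with the default space); otherwise `n_configs` in total.
#' @param space A configuration space (default [config_space()] for the
#'   data's feature count).
#' @param seed Integer seed governing configuration sampling, fold assignment
#'   and the stochastic backends.
#' @param progress Print one line per evaluated configuration.
#' @return An object of class `stab_search` with elements `results` (tibble:
#'   configuration columns, `error`, `size`, one column per stability
#'   measure, `note`), `ensembles` (list of [selection_ensemble()]s),
#'   `folds`, `seed`, `label`, `data_info`. [tidy()] returns the results
#'   tibble, [glance()] a one-row summary including the best error `c_star`.
#' @seealso [desirable_configurations()] for the downstream Pareto analysis.
#' @export
random_search <- function(data, label = "class", n_configs = 100,
                          per_method = FALSE, folds = 10, measures = NULL,
                          alphas = c(0, 1, 2, 10), space = NULL, seed = NULL,
                          progress = FALSE) {
  y <- label_vector(data, label)
  p <- ncol(data) - 1L
  if (is.null(space)) space <- config_space(p)
  if (!is.null(seed)) set.seed(seed)
  configs <- sample_configurations(space, n_configs, per_method = per_method)
  splits <- cv_splits(y, folds)
  cor <- if (needs_cor(measures)) feature_correlations(data, label) else NULL

  # one filter ranking per (fold, filter): top-k selections are nested in k
  # (for MRMR by the prefix property of greedy forward selection), so each
  # configuration just takes the first n_feats entries.
  filters_used <- unique(configs$filter)
  rankings <- lapply(seq_len(folds), function(f) {
    tr <- data[splits[[f]]$train, , drop = FALSE]
    out <- list()
    for (fl in setdiff(filters_used, "none")) {
      out[[fl]] <- switch(fl,
        variance = ranked_indices(filter_variance(tr, label)),
        auc = ranked_indices(filter_auc(tr, label)),
        mrmr = mrmr_ranked(tr, label, max(configs$n_feats[configs$filter == "mrmr"]))
      )
    }
    out
  })

  measure_ids <- names(measure_registry(alphas))
  if (!is.null(measures)) measure_ids <- intersect(measure_ids, measures)
  results <- vector("list", nrow(configs))
  ensembles <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    row <- configs[ci, ]
    res <- tryCatch(
      {
        cfg <- config_from_row(dplyr::mutate(
          row,
          n_feats = pmin(.data$n_feats, p)
        ))
        ev <- eval_with_rankings(
          data, cfg, label, splits, rankings, cor, measure_ids, alphas
        )
        ensembles[[ci]] <- ev$ensemble
        stab <- stats::setNames(ev$stability$value, ev$stability$measure)
        dplyr::bind_cols(
          row,
          tibble::tibble(error = ev$error, size = ev$size),
          tibble::as_tibble(as.list(stab)),
          tibble::tibble(note = NA_character_)
        )
      },
      error = function(e) {
        dplyr::bind_cols(
          row,
          tibble::tibble(
            error = NA_real_, size = NA_real_, note = conditionMessage(e)
          )
        )
      }
    )
    results[[ci]] <- res
    if (progress) {
      message(sprintf(
        "[%d/%d] %s+%s: error %.3f size %.1f",
        ci, nrow(configs), row$filter, row$classifier,
        res$error %||% NA, res$size %||% NA
      ))
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(results),
      ensembles = ensembles,
      folds = folds,
      seed = seed,
      label = label,
      data_info = list(n = nrow(data), p = p)
    ),
    class = "stab_search"
  )
}

ranked_indices <- function(scores) {
  scores$index[order(-scores$score, scores$index)]
}

mrmr_ranked <- function(train, label, k) {
  scores <- filter_mrmr(train, label, k = k)
  scores$index[order(scores$rank, na.last = NA)]
}

# evaluate one configuration on precomputed splits + filter rankings
eval_with_rankings <- function(data, config, label, splits, rankings, cor,
                               measure_ids, alphas) {
  p <- ncol(data) - 1L
  folds <- length(splits)
  fold_errors <- numeric(folds)
  sets <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- data[splits[[f]]$train, , drop = FALSE]
    te <- data[splits[[f]]$test, , drop = FALSE]
    keep <- if (config$filter == "none") {
      seq_len(p)
    } else {
      sort(rankings[[f]][[config$filter]][seq_len(config$n_feats)])
    }
    x <- feature_matrix(tr, label)[, keep, drop = FALSE]
    y <- label_vector(tr, label)
    xtest <- feature_matrix(te, label)[, keep, drop = FALSE]
    backend <- get_backend(config$classifier)
    fit <- backend$fit(x, y, config$params, xtest)
    pred <- ifelse(fit$prob > 0.5, levels(y)[2L], levels(y)[1L])
    fold_errors[f] <- mean(pred != as.character(te[[label]]))
    sets[[f]] <- keep[fit$selected]
  }
  ens <- selection_ensemble(sets, p = p, features = setdiff(names(data), label))
  new_stab_eval(
    config, fold_errors, ens, cor, measure_ids, alphas, folds, NULL
  )
}

#' @export
print.stab_search <- function(x, ...) {
  ok <- !is.na(x$results$error)
  cat(sprintf(
    "<stab_search> %d configurations (%d failed), %d-fold CV on n = %d, p = %d\n",
    nrow(x$results), sum(!ok), x$folds, x$data_info$n, x$data_info$p
  ))
  if (any(ok)) {
    cat(sprintf("  best mean misclassification rate c* = %.4f\n",
      min(x$results$error[ok])
    ))
  }
  invisible(x)
}

#' @rdname random_search
#' @param x A `stab_search` object.
#' @param ... Unused.
#' @export
tidy.stab_search <- function(x, ...) x$results

#' @rdname random_search
#' @export
glance.stab_search <- function(x, ...) {
  ok <- !is.na(x$results$error)
  tibble::tibble(
    n_configs = nrow(x$results),
    n_failed = sum(!ok),
    folds = x$folds,
    n = x$data_info$n,
    p = x$data_info$p,
    c_star = if (any(ok)) min(x$results$error[ok]) else NA_real_
  )
}
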