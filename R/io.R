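#' Read a labeled data set from CSV
#'
#' Reads a comma-separated file (UTF-8, header row, `.` decimal) with one
#' binary label column and metric feature columns, and validates it as input
#' for the filters and the evaluation engine: no missing values, unique
#' column names, both classes present. Validation failures name the offending
#' cell.
#'
#' @param path CSV file path.
#' @param label Name of the label column (default `"class"`).
#' @return A tibble with the label column first (as a two-level factor).
#' @export
read_dataset <- function(path, label = "class") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label %in% names(raw)) {
    stop_format(sprintf("Label column '%s' not found in %s.", label, path))
  }
  if (anyDuplicated(names(raw))) {
    stop_format("Column names must be unique.")
  }
  feats <- setdiff(names(raw), label)
  if (!length(feats)) {
    stop_format("No feature columns besides the label.")
  }
  for (cn in feats) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop_format(sprintf(
        "Non-numeric value in column '%s', row %d.", cn,
        if (is.na(bad)) which(is.na(v))[1] else bad
      ))
    }
    if (anyNA(v)) {
      stop_format(sprintf(
        "Missing value in column '%s', row %d.", cn, which(is.na(v))[1]
      ))
    }
  }
  if (anyNA(raw[[label]])) {
    stop_format(sprintf(
      "Missing value in label column '%s', row %d.",
      label, which(is.na(raw[[label]]))[1]
    ))
  }
  y <- label_vector(raw, label)
  out <- tibble::as_tibble(raw)
  out[[label]] <- y
  dplyr::relocate(out, dplyr::all_of(label))
}

#' Write and re-read evaluation results
#'
#' Serialises a results tibble (as produced by [tidy()] on a
#' [random_search()] object) to CSV or JSON so that reading it back restores
#' every field exactly, including undefined stability values, which are
#' written as empty cells (CSV) or `null` (JSON) — never as a numeric
#' sentinel. Numeric fields are written with full (17 significant digits)
#' precision; column order is stable.
#'
#' @param results A results data frame (or a `stab_search` object).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `write_results()` returns `path` invisibly; `read_results()` the
#'   restored tibble.
#' @export
write_results <- function(results, path, format = NULL) {
  results <- as_results(results)
  if (nrow(results) == 0L) {
    stop_shape("`results` must contain at least one row.")
  }
  format <- format %||% guess_format(path)
  if (format == "json") {
    jsonlite::write_json(
      list(
        columns = names(results),
        rows = results
      ),
      path,
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = I(17)
    )
  } else {
    out <- results
    for (cn in names(out)) {
      if (is.numeric(out[[cn]])) {
        v <- sprintf("%.17g", out[[cn]])
        v[is.na(out[[cn]])] <- NA_character_
        out[[cn]] <- v
      }
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(obj$rows)
    out <- out[, obj$columns, drop = FALSE]
  } else {
    out <- tibble::as_tibble(
      utils::read.csv(path, check.names = FALSE, na.strings = "")
    )
  }
  for (cn in intersect(c("config_id", "n_feats"), names(out))) {
    out[[cn]] <- as.integer(out[[cn]])
  }
  if ("note" %in% names(out)) out$note <- as.character(out$note)
  out
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' Read and write selection ensembles
#'
#' Two interchange formats for the `m` selected feature sets:
#' * JSON: an object with fields `p`, optional `features` (names) and `sets`
#'   (a list of lists of feature names, or of 1-based indices when no names
#'   are recorded).
#' * Plain text: one set per line, whitespace-separated identifiers (feature
#'   names if known, else 1-based indices); `p` must then be supplied by the
#'   caller on reading.
#'
#' @param ens A [selection_ensemble()].
#' @param path File path; format guessed from the `.json` extension unless
#'   `format` is given.
#' @param format `"json"` or `"text"`.
#' @param p,features Total feature count and optional feature names, required
#'   when reading the text format.
#' @return `write_feature_sets()` returns `path` invisibly;
#'   `read_feature_sets()` a [selection_ensemble()].
#' @export
write_feature_sets <- function(ens, path, format = NULL) {
  format <- format %||% if (guess_format(path) == "json") "json" else "text"
  ids <- function(v) if (is.null(ens$features)) v else ens$features[v]
  if (format == "json") {
    jsonlite::write_json(
      list(
        p = ens$p,
        features = ens$features,
        sets = lapply(ens$sets, ids)
      ),
      path,
      auto_unbox = FALSE, null = "null", digits = NA
    )
  } else {
    writeLines(
      vapply(ens$sets, function(v) paste(ids(v), collapse = " "), character(1)),
      path
    )
  }
  invisible(path)
}

#' @rdname write_feature_sets
#' @export
read_feature_sets <- function(path, format = NULL, p = NULL, features = NULL) {
  format <- format %||% if (guess_format(path) == "json") "json" else "text"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    feats <- if (is.null(obj$features)) NULL else unlist(obj$features)
    sets <- lapply(obj$sets, function(s) {
      v <- unlist(s)
      if (is.null(feats)) as.integer(v) else as.character(v)
    })
    return(selection_ensemble(sets, p = obj$p, features = feats))
  }
  if (is.null(p) && is.null(features)) {
    stop_format("Reading the text format requires `p` (or `features`).")
  }
  if (is.null(p)) p <- length(features)
  lines <- readLines(path)
  sets <- lapply(lines, function(l) {
    v <- strsplit(trimws(l), "\\s+")[[1]]
    if (is.null(features)) as.integer(v) else v
  })
  selection_ensemble(sets, p = p, features = features)
}

#' Read a configuration space from YAML or JSON
#'
#' The file mirrors the structure of [config_space()]: top-level `filters`
#' and `classifiers` arrays, an `n_feats` range and a `params` mapping with
#' one `{type, min, max}` entry per hyperparameter (`type` is `"int"` for
#' integer ranges or `"log2"` for values drawn as 2^x with x uniform on
#' [min, max]).
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A space list as produced by [config_space()].
#' @export
read_config_space <- function(path) {
  space <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_format("Reading YAML spaces requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  needed <- c("filters", "classifiers", "n_feats", "params")
  missing <- setdiff(needed, names(space))
  if (length(missing)) {
    stop_format(sprintf(
      "Configuration space lacks fields: %s.", paste(missing, collapse = ", ")
    ))
  }
  space$filters <- as.character(unlist(space$filters))
  space$classifiers <- as.character(unlist(space$classifiers))
  space
}
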