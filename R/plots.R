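#' Plot a random search in stability/size space
#'
#' Scatter plot of the evaluated configurations: mean number of used features
#' (log scale) against `1 - stability` for one measure, coloured by the mean
#' misclassification rate. The view in which the accuracy-band Pareto
#' analysis operates.
#'
#' @param object A `stab_search` object (or its results tibble).
#' @param measure Stability measure column to display (default `"SC"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stab_search <- function(object, measure = "SC", ...) {
  plot_criteria(as_results(object), measure)
}

plot_criteria <- function(results, measure) {
  keep <- !is.na(results$error) & !is.na(results[[measure]])
  df <- results[keep, , drop = FALSE]
  df$instability <- 1 - df[[measure]]
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$size, y = .data$instability, colour = .data$error)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "mean number of chosen features",
      y = paste0("1 - ", measure),
      colour = "error"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Pareto front over the configurations it was extracted from
#'
#' @param front A front from [desirable_configurations()].
#' @param all Optionally the full results tibble (or `stab_search` object) to
#'   show as background points.
#' @return A ggplot object.
#' @export
plot_front <- function(front, all = NULL) {
  measure <- attr(front, "measure") %||% "stability"
  p <- ggplot2::ggplot(
    front,
    ggplot2::aes(x = .data$size, y = .data$instability, colour = .data$error)
  )
  if (!is.null(all)) {
    bg <- as_results(all)
    keep <- !is.na(bg$error) & !is.na(bg[[measure]])
    bg <- bg[keep, , drop = FALSE]
    bg$instability <- 1 - bg[[measure]]
    p <- p + ggplot2::geom_point(data = bg, colour = "grey80", alpha = 0.6)
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_step(direction = "vh", linetype = 3, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "mean number of chosen features",
      y = paste0("1 - ", measure),
      colour = "error"
    ) +
    ggplot2::theme_minimal()
}
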