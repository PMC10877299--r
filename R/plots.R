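# Plotting: scatter plots with the fitted line for single fits, and the
# correlation-comparison bar chart across indices.  Shape mirrors the
# published figures (best-fit scatter plots for r2 >= 0.8 pairs and
# per-property correlation bars); no attempt at pixel reproduction.

#' @exportS3Method ggplot2::autoplot
autoplot.qspr_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ti, y = .data$p)) +
    ggplot2::geom_point(colour = "#2c7fb8", size = 2) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "#de2d26"
    ) +
    ggplot2::labs(
      x = object$index %|na|% "topological index",
      y = object$property %|na|% "property",
      title = sprintf(
        "%s ~ %s: r = %.4f, r² = %.4f (n = %d)",
        object$property %|na|% "P", object$index %|na|% "TI",
        object$r, object$r2, object$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of correlation coefficients across indices
#'
#' One panel per property, bars are the Pearson r of each index's fit;
#' the field's standard way of comparing descriptor performance.
#'
#' @param results A `qspr_results` object.
#' @param properties Optional subset of properties to show.
#' @return A ggplot object.
#' @export
plot_correlation <- function(results, properties = NULL) {
  df <- as_tibble(results) |> dplyr::filter(.data$available)
  if (!is.null(properties)) {
    df <- dplyr::filter(df, .data$property %in% properties)
  }
  ord <- attr(results, "index_order") %||% unique(df$index)
  df$index <- factor(df$index, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$r)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~property) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
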