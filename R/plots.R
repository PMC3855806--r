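# ggplot2 displays for the main result types.

#' Plot a recall-precision curve
#'
#' @param cv A `cv_metrics` object with a PR curve, or a tibble from
#'   [pr_curve()].
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(cv) {
  curve <- if (inherits(cv, "cv_metrics")) cv$pr_curve else cv
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_metrics
#' @export
autoplot.cv_metrics <- function(object, ...) plot_pr_curve(object)

#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$statistic,
                                    y = -log10(.data$q_value),
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$q_cutoff),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#d7301f")) +
    ggplot2::labs(x = "|Welch t|", y = "-log10 q-value",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @method autoplot ranking_result
#' @export
autoplot.ranking_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$positive)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = "Manifold relevance score", y = "Proteins",
                  fill = "positive") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
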