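#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an exact genetic-value distribution
#'
#' Control and case probability mass over normalized odds (log2 x axis).
#'
#' @param object A [exact_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot genetic_value_dist
#' @export
autoplot.genetic_value_dist <- function(object, ...) {
  d <- object$values |>
    tidyr::pivot_longer(c("control_prob", "case_prob"),
                        names_to = "population", values_to = "prob") |>
    dplyr::mutate(population = ifelse(.data$population == "case_prob",
                                      "cases", "controls"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$norm_odds, y = .data$prob,
                                  colour = .data$population)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$norm_odds, yend = 0),
                          linewidth = 0.8) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "normalized genetic odds (population mean = 1)",
                  y = "probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a reclassification table
#'
#' Heatmap of the 3x3 movement between two classifications.
#'
#' @param object A [reclassification_metrics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reclassification
#' @export
autoplot.reclassification <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$prop))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "later classification", y = "earlier classification",
                  fill = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot a drift timeline
#'
#' Panel size, Higher-Risk proportion and AUC over the time points.
#'
#' @param object A [drift_timeline()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drift_timeline
#' @export
autoplot.drift_timeline <- function(object, ...) {
  d <- object$by_time |>
    dplyr::select("time_point", "n_snps", "prop_higher", "auc_empirical") |>
    tidyr::pivot_longer(-"time_point", names_to = "measure")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_point, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
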