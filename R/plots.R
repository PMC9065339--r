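#' @importFrom ggplot2 ggplot aes geom_boxplot geom_col geom_line geom_abline
#'   labs facet_wrap position_dodge theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Boxplots of normalised features by class
#'
#' One panel per feature, binding-site versus non-binding residues on the
#' min-max-normalised scale.
#'
#' @param object A `feature_summary` from [normalize_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_summary <- function(object, ...) {
  ggplot(object$values,
         aes(x = factor(.data$label, labels = c("non-binding", "binding")),
             y = .data$value, fill = factor(.data$label))) +
    geom_boxplot(show.legend = FALSE) +
    facet_wrap(~feature, nrow = 1) +
    labs(x = NULL, y = "normalised value") +
    theme_minimal()
}

#' ROC curve for an evaluation report
#'
#' Plots the empirical ROC of the pooled predictions attached to the
#' report; errors if the report carries no scores.
#'
#' @param object A `site_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_eval <- function(object, ...) {
  pr <- object$predictions
  if (is.null(pr)) abort("evaluation report carries no scores; no ROC")
  ord <- order(pr$score, decreasing = TRUE)
  truth <- pr$truth[ord]
  tpr <- c(0, cumsum(truth == 1) / sum(truth == 1))
  fpr <- c(0, cumsum(truth == 0) / sum(truth == 0))
  ggplot(tibble(fpr = fpr, tpr = tpr), aes(.data$fpr, .data$tpr)) +
    geom_line() +
    geom_abline(linetype = "dashed", colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("%s  AUC = %.4f", object$protocol, object$AUC)) +
    theme_minimal()
}

#' Per-class frequency histogram plot
#'
#' @param hist Tibble from [frequency_histogram()].
#' @return A ggplot object.
#' @export
plot_frequency_histogram <- function(hist) {
  ggplot(hist, aes(.data$midpoint, .data$frequency,
                   fill = factor(.data$label))) +
    geom_col(position = position_dodge(),
             width = (hist$upper[1] - hist$lower[1]) * 0.9) +
    labs(x = "value", y = "frequency", fill = "class") +
    theme_minimal()
}

#' High/low property proportions plot
#'
#' @param props Tibble from [hqi_proportions()].
#' @return A ggplot object.
#' @export
plot_hqi_proportions <- function(props) {
  long <- tidyr::pivot_longer(props, c("high_pct", "low_pct"),
                              names_to = "side", values_to = "pct")
  ggplot(long, aes(.data$index, .data$pct, fill = .data$side)) +
    geom_col() +
    labs(x = NULL, y = "% of binding-site residues", fill = NULL) +
    theme_minimal()
}
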