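#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ROC curve of a splicing-event screen
#'
#' @param object a `screen_result` from [isis_lasso_select()] or
#'   [screen_ases()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.screen_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Splicing-event classifier ROC (AUC = %.3f, %s)",
                      object$auc, object$auc_type)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of modulation-mode counts
#'
#' @param triplets annotated triplet tibble from [annotate_modes()].
#' @return A ggplot.
#' @export
plot_mode_counts <- function(triplets) {
  counts <- mode_counts(triplets)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$mode, y = .data$n,
                                       fill = .data$mode)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "TF modulation mode", y = "Significant triplets") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for a median-split risk stratification
#'
#' @param group,time,event per-subject group label, follow-up time and 0/1
#'   event indicator (see [km_coordinates()]).
#' @return A ggplot of the two survival step curves.
#' @export
plot_km <- function(group, time, event) {
  km <- km_coordinates(group, time, event)
  anchor <- dplyr::distinct(km, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot2::ggplot(
    dplyr::bind_rows(anchor, km[, c("group", "time", "survival")]),
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  ) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(high = "#b2182b",
                                            low = "#2166ac")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Risk group") +
    ggplot2::theme_minimal()
}
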