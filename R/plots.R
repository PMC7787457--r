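# ggplot2 visualizations for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col labs theme_minimal scale_fill_gradient2 facet_wrap
#'   geom_hline
#' @export
ggplot2::autoplot

#' Plot a forecast trajectory
#'
#' Predicted HF risk against forecast step for each patient in the
#' forecast table.
#'
#' @param object An `hf_forecast`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hf_forecast <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$step_ahead / 2, y = .data$hf_prob,
             group = .data$patient_id)) +
    geom_line(alpha = 0.5) +
    geom_point(size = 0.8) +
    labs(x = "Years ahead", y = "Predicted HF probability",
         title = "Auto-regressive HF risk trajectories") +
    theme_minimal()
}

#' Plot a training loss history
#'
#' @param model A trained `hf_model`.
#' @return A ggplot of the per-epoch loss components.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history)) {
    stop_hftraj("model has no training history", "contract_error")
  }
  h <- tidyr::pivot_longer(model$history, -"epoch",
                           names_to = "component", values_to = "value")
  h <- dplyr::filter(h, !is.na(.data$value))
  ggplot(h, aes(x = .data$epoch, y = .data$value,
                colour = .data$component)) +
    geom_line() +
    labs(x = "Epoch", y = "Loss (per-patient mean of summed step losses)",
         colour = NULL, title = "Training loss history") +
    theme_minimal()
}

#' Hinton-style map of first-layer input weights
#'
#' @param model An `hf_model`.
#' @return A ggplot tile map of signed first-dense-layer weights, inputs in
#'   rows and hidden units in columns.
#' @export
plot_input_weights <- function(model) {
  td <- tidy(model)
  td$input <- factor(td$input, levels = rev(model$encoding$input_columns))
  ggplot(td, aes(x = .data$unit, y = .data$input, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "black", mid = "grey90", high = "white") +
    labs(x = "Hidden unit", y = NULL, fill = "Weight",
         title = "First dense layer: input-to-hidden weights") +
    theme_minimal()
}

#' Plot per-year trajectory metrics
#'
#' @param report A per-year evaluation tibble from [evaluate_trajectory()].
#' @param metric Column to plot (default `"f1"`).
#' @return A ggplot.
#' @export
plot_trajectory_metrics <- function(report, metric = "f1") {
  ggplot(report, aes(x = .data$year, y = .data[[metric]])) +
    geom_line() +
    geom_point() +
    labs(x = "Forecast year", y = toupper(metric),
         title = "Trajectory prediction performance by year") +
    theme_minimal()
}
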