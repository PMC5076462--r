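# ggplot2 displays for the result objects.

#' Plot item mean RTs against the similarity predictor
#'
#' One point per item (mean RT over subjects) with the exponentiated
#' model-predicted RT curve of the cosine model overlaid -- the standard
#' display for item-level priming results.
#'
#' @param object A `priming_analysis` from [run_experiment_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot priming_analysis
#' @export
autoplot.priming_analysis <- function(object, ...) {
  ggplot2::ggplot(object$item_means,
                  ggplot2::aes(x = .data$predictor_value, y = .data$mean_rt)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(
      data = object$predicted_curve,
      ggplot2::aes(x = .data[[object$predictor]], y = .data$predicted_rt),
      linewidth = 1
    ) +
    ggplot2::labs(x = paste(object$predictor, "similarity"),
                  y = "mean RT (ms)") +
    ggplot2::theme_minimal()
}

#' Plot the similarity-class composition of an item set
#'
#' Histogram of emitted clamped cosines with the class boundaries
#' overlaid, showing how evenly the stratified generation filled the
#' classes.
#'
#' @param object An `item_set` from [generate_item_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot item_set
#' @export
autoplot.item_set <- function(object, ...) {
  ggplot2::ggplot(object$word_pairs, ggplot2::aes(x = .data$cosine)) +
    ggplot2::geom_histogram(breaks = c(object$scheme$lo, 1),
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$scheme$lo, linetype = 3,
                        alpha = 0.4) +
    ggplot2::labs(x = "clamped cosine similarity", y = "word pairs") +
    ggplot2::theme_minimal()
}

#' Plot a reaction-time distribution by trial type
#'
#' @param trials A trial tibble from [simulate_experiment()].
#' @return A ggplot object.
#' @export
plot_rt_distribution <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$rt, fill = .data$trial_type)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "RT (ms)", y = "trials") +
    ggplot2::theme_minimal()
}
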