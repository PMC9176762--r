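#' Plot category probability curves
#'
#' The classical Rasch-Andrich threshold plot: per item, the probability of
#' each response category along the latent trait. Disordered thresholds show
#' up as categories that are never the most probable response.
#'
#' @param object A `gcs_curves` tibble from [category_probability_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcs_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta, y = .data$prob,
                                       colour = factor(.data$category))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$item)) +
    ggplot2::labs(x = "Person location (logits)",
                  y = "Category probability", colour = "Category") +
    ggplot2::theme_minimal()
}

#' Plot person-item targeting
#'
#' Histogram of estimated person locations with the item threshold locations
#' overlaid, showing how well the item thresholds cover the person
#' distribution (skewed targeting is the hallmark of ceiling-dominated
#' scales).
#'
#' @param persons Output of [estimate_persons()].
#' @param fit A [fit_pcm()] result.
#' @param include_extremes Show extreme persons' extrapolated locations.
#' @return A ggplot object.
#' @export
plot_targeting <- function(persons, fit, include_extremes = FALSE) {
  p <- if (include_extremes) persons else persons[!persons$extreme, ]
  thr <- tidy.pcm_fit(fit)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$estimate,
                                     colour = .data$item),
                        linetype = "dashed") +
    ggplot2::labs(x = "Location (logits)", y = "Persons",
                  colour = "Item thresholds") +
    ggplot2::theme_minimal()
}

#' Plot individual-level risk differences
#'
#' Histogram of the per-case differences in predicted 30-day mortality
#' (rescored minus original), optionally faceted by body region when the
#' stratified table is available.
#'
#' @param object A `risk_difference` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_difference <- function(object, ...) {
  ggplot2::ggplot(object$deltas, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Predicted risk difference (rescored - original)",
                  y = "Cases") +
    ggplot2::theme_minimal()
}
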