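#' Plot a session schedule
#'
#' Timeline of trials and probe placements: trial difficulty (ease score of
#' each trial's parameters) over the session with probe positions marked.
#'
#' @param object A `ws_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ws_schedule
#' @export
autoplot.ws_schedule <- function(object, ...) {
  trials <- dplyr::mutate(object$trials, ease = ease_score(object$trials))
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial_global, y = .data$ease)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_vline(
      data = object$probes,
      ggplot2::aes(xintercept = .data$after_trial + 0.5,
                   colour = .data$kind),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::labs(x = "trial", y = "trial ease score", colour = "probe",
                  title = paste("Session schedule:", object$study)) +
    ggplot2::theme_minimal()
}

#' Plot fitted versus observed control ratings
#'
#' Observed control ratings and the model's predictions over the rated
#' trials of one participant.
#'
#' @param object A `ws_control_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ws_control_fit
#' @export
autoplot.ws_control_fit <- function(object, ...) {
  d <- tibble::tibble(
    trial = rep(object$trial_index, 2),
    rating = c(object$observed, object$fitted),
    series = rep(c("observed", "fitted"), each = length(object$trial_index))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$rating,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "trial", y = "control rating (0-100)", colour = NULL,
      subtitle = sprintf("r(fitted, actual) = %.2f", object$r_fitted_actual)
    ) +
    ggplot2::theme_minimal()
}

#' Plot timepoint contrasts
#'
#' Estimated timepoint contrasts per group with normal-theory 95% error
#' bars; the difference row is drawn in its own facet.
#'
#' @param object A `ws_contrasts` tibble from [emm_timepoint_contrasts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ws_contrasts
#' @export
autoplot.ws_contrasts <- function(object, ...) {
  d <- dplyr::mutate(object,
                     lo = .data$estimate - 1.96 * .data$std_error,
                     hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~ .data$contrast, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "stress change (slider units)") +
    ggplot2::theme_minimal()
}

#' Plot stress against subjective control
#'
#' Scatter of aligned stress ratings against mean subjective control with a
#' linear trend, the raw-data view of the coupling analysis.
#'
#' @param aligned Aligned table from [align_probes_to_stress()] (with a
#'   `stress` column).
#' @return A ggplot object.
#' @export
plot_stress_coupling <- function(aligned) {
  stopifnot(all(c("control", "stress") %in% names(aligned)))
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$control, y = .data$stress)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = "subjective control (0-100)",
                  y = "subjective stress (0-100)") +
    ggplot2::theme_minimal()
}
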