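#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$concentration, .data$area)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Standard concentration (µg/mL)", y = "Peak area",
      title = sprintf("y = %.4g x %+.4g   R² = %.4f",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.translocation_score <- function(object, ...) {
  thr <- object$geometry$positivity_threshold
  ggplot2::ggplot(object$records, ggplot2::aes(.data$ratio,
                                               fill = .data$positive)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "seagreen")) +
    ggplot2::labs(x = "Nuclear / perinuclear intensity ratio",
                  y = "Cells",
                  fill = sprintf("ratio > %g", thr)) +
    ggplot2::theme_minimal()
}

#' Plot a clamp trace with its detected steady-state window
#'
#' Blood glucose and glucose infusion rate over time, with the steady-state
#' window shaded when provided.
#'
#' @param trace A clamp-trace tibble (`time`, `glucose`, `gir`).
#' @param steady Optional one-row tibble from [detect_steady_state()].
#' @return A ggplot object (faceted by variable).
#' @export
plot_clamp_trace <- function(trace, steady = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(trace, "time", "glucose", "gir"),
    cols = c("glucose", "gir"),
    names_to = "variable", values_to = "value"
  )
  long$variable <- factor(long$variable, levels = c("glucose", "gir"),
                          labels = c("Blood glucose (mM)",
                                     "GIR (mg/kg/min)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(steady) && isTRUE(steady$steady[1])) {
    p <- p + ggplot2::annotate("rect",
                               xmin = steady$t_start[1], xmax = steady$t_end[1],
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "seagreen")
  }
  p
}

#' Plot a tracer plasma decay with its trapezoid sampling
#'
#' @param plasma A plasma tibble (`time`, `plasma_dpm`).
#' @return A ggplot object.
#' @export
plot_tracer_decay <- function(plasma) {
  ggplot2::ggplot(plasma, ggplot2::aes(.data$time, .data$plasma_dpm)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time after bolus (min)", y = "Plasma DPM") +
    ggplot2::theme_minimal()
}
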