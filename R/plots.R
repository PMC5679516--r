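#' Plot yearly collapse-probability series with credible ribbons
#'
#' Posterior mean collapse probability by year, one colour per stratum, with
#' the credible interval drawn as a ribbon. The yearly estimates are
#' independent; lines are drawn only to guide the eye.
#'
#' @param series Output of [posterior_series()].
#' @param strata Which strata to draw.
#' @param mark_year Optional vertical reference year (e.g. a policy change).
#' @return A ggplot object.
#' @export
plot_collapse_series <- function(series,
                                 strata = unique(series$stratum),
                                 mark_year = NULL) {
  d <- filter(series, .data$stratum %in% strata)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$year, y = .data$mean,
    colour = .data$stratum, fill = .data$stratum
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(
      x = "Year", y = "Probability of lek collapse",
      colour = "Stratum", fill = "Stratum"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(mark_year)) {
    p <- p + ggplot2::geom_vline(xintercept = mark_year, linetype = "dashed")
  }
  p
}

#' Plot yearly attendance trends by stratum
#'
#' @param summary Output of [annual_summary()].
#' @param mark_year Optional vertical reference year.
#' @return A ggplot object.
#' @export
plot_attendance_trend <- function(summary, mark_year = NULL) {
  p <- ggplot2::ggplot(
    filter(summary, .data$stratum != "total"),
    ggplot2::aes(x = .data$year, y = .data$males_per_lek, colour = .data$stratum)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Year", y = "Males per lek", colour = "Stratum") +
    ggplot2::theme_minimal()
  if (!is.null(mark_year)) {
    p <- p + ggplot2::geom_vline(xintercept = mark_year, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of an edge-effect regression
#'
#' Observed yearly points (on the fitted scale) with the OLS line.
#'
#' @param object An [fit_edge_regression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_regression <- function(object, ...) {
  d <- object$data
  d$yfit <- if (object$scale == "logit") qlogis(d$probability) else d$probability
  ggplot2::ggplot(d, ggplot2::aes(x = .data$density, y = .data$yfit)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$beta,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Well density (wells/km2, lagged)",
      y = if (object$scale == "logit") "logit collapse probability" else "Collapse probability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a predicted attendance-change curve
#'
#' @param object An [predict_attendance_change()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attendance_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$pct_change)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "Adjacent well density (wells/km2)",
      y = "Predicted change in core lek attendance (%)"
    ) +
    ggplot2::theme_minimal()
}
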