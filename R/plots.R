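#' Plot a simulated trajectory
#'
#' Gastric masses, viscosity, secretion and absorption rates against time,
#' faceted by quantity.
#'
#' @param object A `gastro_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gastro_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "nutrient_g", "liquid_g", "total_g",
                          "viscosity_pa_s", "secretion_g_s",
                          "absorption_g_s")],
    -"time_s", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 60, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}

#' Plot a fitted emptying curve against its data
#'
#' @param object A `gastro_fit` from [fit_feedback_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gastro_fit <- function(object, ...) {
  r <- object$residuals
  if (!all(c("time_s", "observed", "fitted") %in% names(r))) {
    return(ggplot2::ggplot(r, ggplot2::aes(seq_along(.data$residual),
                                           .data$residual)) +
             ggplot2::geom_col() +
             ggplot2::labs(x = "residual index", y = "residual"))
  }
  ggplot2::ggplot(r, ggplot2::aes(.data$time_s / 60)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (min)", y = "gastric content")
}

#' Histogram the Monte-Carlo parameter samples
#'
#' @param object A `gastro_mc` from [run_monte_carlo()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gastro_mc <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(.data$estimate)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "estimate", y = "count")
}

#' Plot a sensitivity series
#'
#' @param object A `gastro_sensitivity` from [sensitivity_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gastro_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s / 60, .data$s_star)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("S* (%s)", attr(object, "param")))
}
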