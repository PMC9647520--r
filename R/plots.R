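# ggplot2 displays for fitted objects

#' Plot a smooth lag-coefficient function
#'
#' Draws the estimated coefficient function over the lag window with a
#' pointwise 95\% band, marking lags flagged at `alpha`.
#'
#' @param object a `smooth_lag_fit`.
#' @param alpha flagging level for the highlighted lags.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.smooth_lag_fit <- function(object, alpha = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$flagged <- d$p.value < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "lag (days)", y = "standardized coefficient",
                  title = paste0(attr(object, "predictor"), " → ",
                                 attr(object, "outcome"))) +
    ggplot2::theme_minimal()
}

#' Plot retained confirmatory lag coefficients
#'
#' @param object a `lag_model_fit` or `final_lag_model`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lag_model_fit <- function(object, ...) {
  d <- object$coefficients
  if (!nrow(d)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no significant lag identified") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$estimate,
                                  colour = .data$path)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "lag (days)", y = "coefficient",
                  title = paste0(object$predictor, " → ",
                                 object$outcome)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lag_model_fit
#' @export
autoplot.final_lag_model <- function(object, ...) autoplot(object$fit, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
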