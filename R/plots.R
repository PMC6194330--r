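# ggplot2 methods for lag profiles.

#' Plot a lag profile
#'
#' Stem plot of the per-lag coefficients with the surrogate confidence
#' band (when present) drawn as a ribbon. With `log_scale = TRUE` the
#' profile is drawn as points and lines in log-log coordinates (lag 0
#' and non-positive values are dropped), the rendering that
#' distinguishes power-law from exponential decay.
#'
#' @param object A `lag_profile`.
#' @param log_scale Draw in log-log coordinates?
#' @param clip_negative Clip small negative coefficients to zero for
#'   display (tables are never clipped)?
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lag_profile <- function(object, log_scale = FALSE,
                                 clip_negative = FALSE, ...) {
  kind <- toupper(attr(object, "kind"))
  ylab <- if (isTRUE(attr(object, "normalized"))) kind
          else paste0(kind, " [bit]")
  df <- tibble::as_tibble(object)
  if (clip_negative) df$value <- pmax(df$value, 0)
  has_band <- "ci_low" %in% names(df) && any(!is.na(df$ci_low))
  if (log_scale) {
    df <- df[df$lag >= 1 & df$value > 0, ]
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value))
    if (has_band)
      g <- g + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = pmax(.data$ci_low, .Machine$double.xmin),
                     ymax = pmax(.data$ci_high, .Machine$double.xmin)),
        fill = "steelblue", alpha = 0.3)
    g + ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "lag", y = ylab) + ggplot2::theme_minimal()
  } else {
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value))
    if (has_band)
      g <- g + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
        fill = "steelblue", alpha = 0.3)
    g + ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
      ggplot2::labs(x = "lag", y = ylab) + ggplot2::theme_minimal()
  }
}
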