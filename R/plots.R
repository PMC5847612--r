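#' Plot methods
#'
#' `autoplot()` methods render the package's result types with ggplot2:
#' kymographs as rasters (time increasing downwards, as in kymograph
#' figures), border trajectories as position-vs-time curves with
#' change-point markers, interval distributions as lag-coloured
#' histograms, ROI series as time courses, and somite records as the
#' interval-size scatter with its OLS line.
#'
#' @param object the object to plot.
#' @param ... further arguments (see individual methods).
#' @return A ggplot.
#' @name stepkymo-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname stepkymo-plots
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(t_min = object$t_min,
                           position_um = object$position_um)
  df$value <- as.vector(t(object$data))
  ggplot2::ggplot(df, ggplot2::aes(.data$position_um, .data$t_min,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = mean(range(df$value,
                                                        na.rm = TRUE)),
                                  name = "FRET/CFP") +
    ggplot2::labs(x = "Position from anterior end (µm)",
                  y = "Time (min)")
}

#' @rdname stepkymo-plots
#' @param change_points optional [detect_change_points()] result to mark.
#' @export
autoplot.border_trajectory <- function(object, change_points = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t_min,
                                            .data$position_um)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Time (min)",
                  y = "Border position (µm)",
                  subtitle = sprintf("isoline level %.3f",
                                     attr(object, "level")))
  if (!is.null(change_points) && nrow(change_points) > 0) {
    pos_at <- object$position_um[match(change_points$frame, object$frame)]
    p <- p + ggplot2::annotate("point", x = change_points$time_min,
                               y = pos_at, shape = 25, fill = "red",
                               size = 2.5)
  }
  p
}

#' @rdname stepkymo-plots
#' @param binwidth_min histogram bin width in minutes.
#' @param max_lag lags above this are pooled into one colour class.
#' @export
autoplot.interval_distribution <- function(object, binwidth_min = 5,
                                           max_lag = 4, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    lag_class = factor(pmin(.data$lag, max_lag),
                       levels = seq_len(max_lag),
                       labels = c(as.character(seq_len(max_lag - 1)),
                                  paste0(">=", max_lag))))
  ggplot2::ggplot(df, ggplot2::aes(.data$interval_min,
                                   fill = .data$lag_class)) +
    ggplot2::geom_histogram(binwidth = binwidth_min, boundary = 0,
                            position = "stack", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("red", "blue", "green3",
                                          "yellow2"),
                               name = "lag (steps)") +
    ggplot2::labs(x = "Interval (min)", y = "Count")
}

#' @rdname stepkymo-plots
#' @export
autoplot.roi_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_min, .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time (min)", y = "Mean FRET/CFP ratio")
}

#' @rdname stepkymo-plots
#' @export
autoplot.somite_records <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$preceding_interval_min,
                                       .data$size_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "Step interval (min)", y = "Somite size (µm)")
}
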