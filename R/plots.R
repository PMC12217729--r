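#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metric curve with its interdecile band and fit
#'
#' @param object a `metric_curve`.
#' @param show_fit overlay the fitted power model. Default TRUE.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metric_curve <- function(object, show_fit = TRUE, ...) {
  df <- tibble::as_tibble(object)
  fit <- attr(object, "fit")
  kind <- attr(object, "kind")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$abscissa)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), na.rm = TRUE) +
    ggplot2::labs(
      x = if (identical(kind, "mfp")) "displacement threshold D (cm)"
          else "walked distance s (cm)",
      y = switch(kind %||% "value",
                 diffusivity = "mean squared displacement (cm^2)",
                 mfp = "mean first-passage walked distance (cm)",
                 coverage = "covered fraction of accessible area",
                 selfcross = "cumulative self-crossings",
                 "value"),
      title = kind)
  if (show_fit && !is.null(fit) && is.finite(fit$b %||% NA)) {
    xx <- df$abscissa[df$abscissa > 0]
    yy <- fit$a * xx^fit$b + (fit$c %||% 0)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(abscissa = xx, fitv = yy),
      ggplot2::aes(y = .data$fitv), linetype = "dashed")
  }
  p
}

#' Quiver plot of a flow map
#'
#' Arrows show the per-cell circular mean movement direction; arrow
#' length scales with the mean resultant length. Masked cells (too few
#' headings) are omitted.
#'
#' @param object a `flow_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flow_map <- function(object, ...) {
  cell <- attr(object, "cell") %||% 2
  df <- tibble::as_tibble(object)
  df <- df[df$included, ]
  df$xend <- df$x + 0.45 * cell * df$resultant * cos(df$direction)
  df$yend <- df$y + 0.45 * cell * df$resultant * sin(df$direction)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  title = "per-cell mean movement direction")
}

#' Heatmap of occupancy time
#'
#' @param heatmap tibble from [occupancy_heatmap()].
#' @return a ggplot.
#' @export
plot_occupancy <- function(heatmap) {
  ggplot2::ggplot(heatmap,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$seconds)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "time (s)",
                  title = "occupancy time")
}

#' Circular histogram of walking orientations
#'
#' @param orientation tibble from [orientation_distribution()].
#' @param bins number of angular bins. Default 36.
#' @return a ggplot.
#' @export
plot_orientation <- function(orientation, bins = 36) {
  ggplot2::ggplot(orientation, ggplot2::aes(x = .data$heading)) +
    ggplot2::geom_histogram(bins = bins, boundary = -pi) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi)) +
    ggplot2::labs(x = "heading (rad, 0 = +x)", y = "count",
                  title = "walking orientation")
}

#' Histogram of hourly short-stop rates
#'
#' @param x a `stop_uniformity` result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stop_uniformity <- function(x, ...) {
  ggplot2::ggplot(x$hourly,
                  ggplot2::aes(x = .data$hour, y = .data$mean_rate)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = x$mean_rate, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = x$ci, linetype = "dotted") +
    ggplot2::labs(x = "hour of day", y = "short-stops per hour",
                  title = sprintf("daily short-stop rates (chi^2 p = %.2g)",
                                  x$p_value))
}
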