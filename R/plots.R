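# ggplot2 views of the main result types. These are convenience displays;
# all quantitative results come from the metric functions.

#' @method autoplot trace_set
#' @export
autoplot.trace_set <- function(object, cells = NULL, offset = 1.5, ...) {
  df <- as_tibble(object)
  if (!is.null(cells)) df <- filter(df, .data$cell %in% cells)
  df <- mutate(df, y = .data$dff + offset * (match(.data$cell,
                                                   sort(unique(.data$cell))) - 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$y,
                                   group = .data$cell)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "dF/F (offset per cell)") +
    ggplot2::theme_minimal()
}

#' Raster plot of spike trains or detected events
#'
#' @param x A `spike_trains` or `event_set` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_raster <- function(x, ...) {
  time_col <- if ("onset" %in% names(x)) "onset" else "time"
  ggplot2::ggplot(x, ggplot2::aes(.data[[time_col]], .data$cell)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "cell") +
    ggplot2::theme_minimal()
}

#' @method autoplot island
#' @export
autoplot.island <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(.data$x, .data$y,
                                             colour = .data$type)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot resilience_curve
#' @export
autoplot.resilience_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$injured_fraction,
                                       .data$active_fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "injured fraction", y = "active fraction of baseline") +
    ggplot2::theme_minimal()
}

#' @method autoplot island_entropy
#' @export
autoplot.island_entropy <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(.data$entropy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "single-cell Markov entropy", y = "cells") +
    ggplot2::theme_minimal()
}

#' @method autoplot fc_network
#' @export
autoplot.fc_network <- function(object, ...) {
  adj <- object$adjacency
  df <- tibble(
    from = rep(object$cells, times = length(object$cells)),
    to = rep(object$cells, each = length(object$cells)),
    connected = as.vector(adj) > 0
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$connected)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "grey20")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "cell", y = "cell", fill = "edge") +
    ggplot2::theme_minimal()
}
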