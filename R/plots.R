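#' Plot decoded finger-activation traces
#'
#' One facet per finger with the decoded signed trace and, optionally, the
#' reference trajectory.
#'
#' @param object a `finger_activation` tibble with a `t` column.
#' @param reference optional `reference_profile` or tibble with `t` and
#'   per-finger columns on the same scale as the decoded traces.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot finger_activation
#' @export
autoplot.finger_activation <- function(object, reference = NULL, ...) {
  stopifnot("t" %in% names(object))
  long <- tidyr::pivot_longer(object[c("t", fingers())],
                              cols = dplyr::all_of(fingers()),
                              names_to = "finger", values_to = "decoded")
  long$finger <- factor(long$finger, fingers())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$decoded), colour = "#c0392b") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$finger)) +
    ggplot2::labs(x = "time (s)", y = "activation") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    if (inherits(reference, "reference_profile")) reference <- reference$targets
    ref_long <- tidyr::pivot_longer(reference[c("t", fingers())],
                                    cols = dplyr::all_of(fingers()),
                                    names_to = "finger",
                                    values_to = "target")
    ref_long$finger <- factor(ref_long$finger, fingers())
    p <- p + ggplot2::geom_line(
      data = ref_long, ggplot2::aes(y = .data$target),
      colour = "grey40", linetype = "dashed"
    )
  }
  p
}

#' Spatial map of per-channel values on the electrode grid
#'
#' Tile map of one value per channel (e.g. a mean RMS map or a spatial
#' filter's weights) laid out on the grid geometry.
#'
#' @param values named or ordered numeric vector, one value per channel
#'   in `channel_ids`.
#' @param geometry a [grid_geometry()].
#' @param channel_ids grid channel ids corresponding to `values`.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_channel_map <- function(values, geometry = grid_geometry(),
                             channel_ids = seq_along(values),
                             title = NULL) {
  pos <- channel_positions(geometry)[channel_ids, ]
  pos$value <- as.numeric(values)
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row", title = title) +
    ggplot2::theme_minimal()
}

#' Plot channel-reduction summary curves
#'
#' Median with interquartile ribbon per method as a function of the
#' electrode-subset size, one facet per metric.
#'
#' @param object a `sweep_result` from [cmd_sweep()].
#' @param metrics which metrics to facet (default nMSE, MAFA and
#'   classification accuracy).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object,
                                  metrics = c("nmse", "mafa", "ca"), ...) {
  d <- object[object$metric %in% metrics, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_channels, y = .data$median,
                                  colour = .data$method,
                                  fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = allowed_subset_sizes()) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of electrodes", y = "median (IQR)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
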