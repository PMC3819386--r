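# ggplot2 helpers for the map and result types.

map_plot_data <- function(map, node_map) {
  stopifnot("node" %in% names(map))
  left_join(map, node_map, by = "node")
}

#' Plot an overlap map as axial voxel slices
#'
#' @param map Overlap tibble (columns `node`, `overlap`).
#' @param node_map Tibble (node, x, y, z).
#' @param slices Optional z slices to show (default: all).
#' @return A ggplot object.
#' @export
plot_overlap <- function(map, node_map, slices = NULL) {
  d <- map_plot_data(map, node_map)
  if (!is.null(slices)) d <- filter(d, .data$z %in% slices)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% subjects") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Top-fraction overlap") +
    ggplot2::theme_minimal()
}

#' Plot a group-difference map as axial voxel slices
#'
#' @param diff Difference tibble (columns `node`, `diff`).
#' @param node_map Tibble (node, x, y, z).
#' @param slices Optional z slices to show.
#' @return A ggplot object.
#' @export
plot_difference <- function(diff, node_map, slices = NULL) {
  d <- map_plot_data(diff, node_map)
  if (!is.null(slices)) d <- filter(d, .data$z %in% slices)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(limits = c(-100, 100),
                                  name = "Δ overlap (pp)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Group difference in overlap") +
    ggplot2::theme_minimal()
}

#' Plot conjunction ROIs as axial voxel slices
#'
#' @param object A `vg_roiset` from [conjunction_rois()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vg_roiset <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data$direction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Conjunction ROIs") +
    ggplot2::theme_minimal()
}

#' Scatter plot of regional efficiency against life satisfaction
#'
#' @param data Data frame with columns `value` (regional metric) and
#'   `swls_total`.
#' @param metric_label Axis label for the regional metric.
#' @return A ggplot object.
#' @export
plot_swls_scatter <- function(data, metric_label = "regional Eglob") {
  ggplot2::ggplot(data, ggplot2::aes(.data$value, .data$swls_total)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = metric_label, y = "SWLS total",
                  title = "Regional integration and life satisfaction") +
    ggplot2::theme_minimal()
}

#' Band-power QC plot of a voxel-wise PSD table
#'
#' @param psd Output of [voxelwise_psd()].
#' @return A ggplot object.
#' @export
plot_psd <- function(psd) {
  d <- mutate(psd, band = factor(paste0(.data$lo_hz, "-", .data$hi_hz,
                                        " Hz")))
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$power)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "frequency band", y = "mean periodogram power",
                  title = "Voxel-wise band power") +
    ggplot2::theme_minimal()
}
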