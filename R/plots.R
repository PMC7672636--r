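# ggplot2 visualisations for result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-slice shared-area profile
#'
#' @param object An `interface_measurement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interface_measurement <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$area_um2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "slice", y = expression("shared area per slice (" * mu * m^2 * ")"),
      title = sprintf("Shared area %s | %s (%s mode): total %.3g um^2",
                      paste(object$label_a, collapse = "+"),
                      paste(object$label_b, collapse = "+"),
                      object$mode, object$total_area_um2)) +
    ggplot2::theme_minimal()
}

#' Histogram of a measurement set
#'
#' @param object A `linear_measurement_set`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linear_measurement_set <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s (%s)", object$quantity, object$units),
                  y = "count", title = format(object)) +
    ggplot2::theme_minimal()
}

#' Histogram of per-mitochondrion volumes
#'
#' @param object A `mitochondria_stats` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot (log10 volume axis).
#' @export
autoplot.mitochondria_stats <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume_nm3)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("mitochondrion volume (" * nm^3 * ")"),
                  y = "count",
                  title = sprintf("%s: %d mitochondria, total %.3g nm^3",
                                  object$cell_id, object$count,
                                  object$total_volume_nm3)) +
    ggplot2::theme_minimal()
}

#' Plot the monolayer adjacency graph
#'
#' Nodes are cells, edges join face-adjacent cells, edge width scales
#' with voxel-face contact area.
#'
#' @param graph An [igraph::igraph] from [adjacency_graph].
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_adjacency <- function(graph, seed = 1L) {
  lay <- withr::with_seed(seed, igraph::layout_with_fr(graph))
  nodes <- tibble::tibble(name = igraph::V(graph)$name,
                          x = lay[, 1], y = lay[, 2])
  el <- igraph::as_edgelist(graph)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el) > 0) {
    edges <- tibble::tibble(
      x = nodes$x[match(el[, 1], nodes$name)],
      y = nodes$y[match(el[, 1], nodes$name)],
      xend = nodes$x[match(el[, 2], nodes$name)],
      yend = nodes$y[match(el[, 2], nodes$name)],
      weight = igraph::E(graph)$weight)
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60")
  }
  p + ggplot2::geom_point(size = 8, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1.6) +
    ggplot2::scale_linewidth(range = c(0.3, 2),
                             name = expression("contact (" * mu * m^2 * ")")) +
    ggplot2::theme_void()
}
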