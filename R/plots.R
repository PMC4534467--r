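#' Plot an islet contact graph
#'
#' Cells as points, shadow-validated contacts as segments, on an equal-scale
#' micrometre canvas.
#'
#' @param object An `islet_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.islet_graph <- function(object, ...) {
  v <- object$vertices
  e <- object$edges |>
    dplyr::left_join(v, by = c("from" = "cell_id")) |>
    dplyr::left_join(v, by = c("to" = "cell_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to),
      colour = "grey40") +
    ggplot2::geom_point(data = v, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a pair distribution function
#'
#' g(r) against the bin centre, with the complete-spatial-randomness
#' reference g = 1 and the 8-13 um contact band shaded.
#'
#' @param object An `islet_pairdist`.
#' @param band Radius band to highlight (um); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.islet_pairdist <- function(object, band = c(8, 13), ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$r, y = .data$g))
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "steelblue")
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (µm)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Plot measure-difference curves of a model sweep
#'
#' One panel per measure, curves over `rlp_d` coloured by `rlp_a`, with the
#' zero line whose crossings are the measure-equilibria.
#'
#' @param curves Output of [difference_curves()].
#' @return A ggplot object.
#' @export
plot_difference_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$rlp_d, y = .data$difference,
                               colour = factor(.data$rlp_a),
                               group = .data$rlp_a)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "rlp_d", y = "simulated - experimental",
                  colour = "rlp_a") +
    ggplot2::theme_minimal()
}

#' Plot measures against neighborhood radius
#'
#' @param measures Tibble from [measure_islets()] aggregated per radius, or
#'   any tibble with `radius` plus measure columns and an optional `group`
#'   column.
#' @param measure Column to plot.
#' @return A ggplot object.
#' @export
plot_measure_vs_radius <- function(measures, measure = "mean_degree") {
  aes <- if ("group" %in% names(measures)) {
    ggplot2::aes(x = .data$radius, y = .data[[measure]],
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$radius, y = .data[[measure]])
  }
  ggplot2::ggplot(measures, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "neighborhood radius (µm)", y = measure) +
    ggplot2::theme_minimal()
}
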