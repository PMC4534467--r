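#' Neighborhood parameters for contact-graph construction
#'
#' Bundles the geometric parameters of the contact rule: the neighborhood
#' radius (maximum centre-to-centre distance, in micrometres, at which two
#' cells can share an edge), the physical cell radius used by the shadow
#' occlusion test, and how the two directed acceptance lists are symmetrised
#' into undirected edges.
#'
#' @param radius Neighborhood radius in micrometres. Islet analyses sweep
#'   5-16 um; the non-random pair-distribution band motivates 8-13 um.
#' @param cell_radius Physical cell radius in micrometres (default 4).
#' @param symmetrize `"mutual"` (edge only when each endpoint accepts the
#'   other; the default, since a physical contact is mutual) or `"union"`.
#' @return A list of class `neighborhood_params`.
#' @export
#' @examples
#' neighborhood_params(radius = 10)
neighborhood_params <- function(radius = 10, cell_radius = 4,
                                symmetrize = c("mutual", "union")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0,
            is.numeric(cell_radius), cell_radius > 0, radius > cell_radius)
  structure(list(radius = radius, cell_radius = cell_radius,
                 symmetrize = symmetrize),
            class = "neighborhood_params")
}

#' Shadow half-angle cast by a contacting cell
#'
#' A cell of radius `cell_radius` at distance `d` subtends a cone of
#' half-angle `atan(cell_radius / d)` at the focal cell; nearer candidate
#' neighbours occlude ("shadow") farther ones inside that cone.
#'
#' @param d Distance(s) to the occluding cell, micrometres; must be positive.
#' @param cell_radius Cell radius in micrometres.
#' @return Half-angle(s) in radians, strictly decreasing in `d`.
#' @export
#' @examples
#' shadow_angle(4)  # pi / 4
shadow_angle <- function(d, cell_radius = 4) {
  if (any(d <= 0)) {
    abort("shadow_angle requires positive distances",
          class = "isletgraph_domain_error")
  }
  atan(cell_radius / d)
}

cells_coord_matrix <- function(cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("cell_id", "x", "y") %in% names(cells)))
  cols <- c("x", "y", if ("z" %in% names(cells)) "z")
  as.matrix(cells[cols])
}

#' Directed shadow-accepted neighbours of one cell
#'
#' Candidates within the neighborhood radius are sorted by distance (ties
#' broken by ascending `cell_id`) and accepted in order unless occluded by an
#' already accepted neighbour, i.e. unless the angular separation from some
#' accepted neighbour falls strictly below that neighbour's [shadow_angle()].
#' Works in 2d and (via the angle between direction vectors) in 3d.
#'
#' @param cells Tibble with `cell_id`, `x`, `y` and optionally `z` columns.
#' @param focal `cell_id` of the focal cell.
#' @param params A [neighborhood_params()].
#' @return Integer vector of accepted `cell_id`s, in traversal order.
#' @export
directed_neighbors <- function(cells, focal, params = neighborhood_params()) {
  cells <- tibble::as_tibble(cells)
  cells <- dplyr::arrange(cells, .data$cell_id)
  idx <- match(focal, cells$cell_id)
  if (is.na(idx)) {
    abort("focal cell not found in `cells`", class = "isletgraph_lookup_error")
  }
  acc <- cpp_directed_neighbors(cells_coord_matrix(cells), idx,
                                params$radius, params$cell_radius)
  cells$cell_id[acc]
}

#' Build the contact graph of one islet
#'
#' Applies the shadow algorithm from every cell and symmetrises the directed
#' acceptance lists into an undirected graph whose vertices are the cells
#' (with their coordinates) and whose edges are shadow-validated contacts at
#' the given neighborhood radius.
#'
#' @param cells Tibble with `cell_id`, `x`, `y` and optionally `z` columns;
#'   at least one row.
#' @param params A [neighborhood_params()].
#' @return An object of class `islet_graph`: a list with `vertices` (tibble),
#'   `edges` (tibble of `from`, `to`, `distance`, with `from < to` by cell
#'   id) and `params`.
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = 1:3, x = c(0, 9, 4.5),
#'                         y = c(0, 0, 7.79))
#' build_islet_graph(cells, neighborhood_params(radius = 10))
build_islet_graph <- function(cells, params = neighborhood_params()) {
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) < 1) {
    abort("an islet graph needs at least one cell",
          class = "isletgraph_value_error")
  }
  cells <- dplyr::arrange(cells, .data$cell_id)
  coords <- cells_coord_matrix(cells)
  if (nrow(cells) >= 2) {
    em <- cpp_shadow_edges(coords, params$radius, params$cell_radius,
                           params$symmetrize == "mutual")
  } else {
    em <- matrix(integer(0), ncol = 2)
  }
  dists <- if (nrow(em) > 0) {
    sqrt(rowSums((coords[em[, 1], , drop = FALSE] -
                  coords[em[, 2], , drop = FALSE])^2))
  } else numeric(0)
  edges <- tibble::tibble(
    from = cells$cell_id[em[, 1]],
    to = cells$cell_id[em[, 2]],
    distance = dists
  )
  structure(list(vertices = cells, edges = edges, params = params),
            class = "islet_graph")
}

#' @export
print.islet_graph <- function(x, ...) {
  dim_lab <- if ("z" %in% names(x$vertices)) "3d" else "2d"
  cat(sprintf(
    "<islet_graph> %d vertices, %d edges (%s, radius %g um, %s)\n",
    nrow(x$vertices), nrow(x$edges), dim_lab, x$params$radius,
    x$params$symmetrize))
  invisible(x)
}

#' Build contact graphs for every islet of a table
#'
#' @param tbl A validated islet table, typically already restricted to beta
#'   cells with [filter_cells()].
#' @param params A [neighborhood_params()].
#' @return A tibble with one row per islet: `group`, `subject_id`,
#'   `islet_id`, `n_cells` and a `graph` list-column of `islet_graph`s.
#' @export
build_islet_graphs <- function(tbl, params = neighborhood_params()) {
  tbl |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$group, .data$subject_id, .data$islet_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      graph = list(build_islet_graph(dplyr::pick(dplyr::everything()),
                                     params)),
      .groups = "drop"
    )
}

#' Fraction of distance-threshold edges removed by shadowing
#'
#' Among all pairs of cells within the neighborhood radius, the fraction that
#' the shadow occlusion test removes from the graph. Returns `NA` when no
#' pair lies within the radius.
#'
#' @param cells Tibble with `cell_id`, `x`, `y` (optionally `z`).
#' @param params A [neighborhood_params()].
#' @return A single number in `[0, 1]`, or `NA`.
#' @export
edge_removal_fraction <- function(cells, params = neighborhood_params()) {
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) < 2) {
    abort("need at least 2 cells", class = "isletgraph_value_error")
  }
  coords <- cells_coord_matrix(cells)
  d <- as.matrix(stats::dist(coords))
  within <- sum(d[upper.tri(d)] <= params$radius)
  if (within == 0) return(NA_real_)
  g <- build_islet_graph(cells, params)
  (within - nrow(g$edges)) / within
}
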