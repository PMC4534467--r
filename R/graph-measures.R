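#' Vertex degrees of an islet graph
#'
#' The degree of a cell is the number of shadow-validated contacts it has,
#' i.e. the number of edges containing it.
#'
#' @param g An `islet_graph`.
#' @return A tibble with `cell_id` and `degree` for every vertex.
#' @export
vertex_degrees <- function(g) {
  stopifnot(inherits(g, "islet_graph"))
  counts <- table(factor(c(g$edges$from, g$edges$to),
                         levels = g$vertices$cell_id))
  tibble::tibble(cell_id = g$vertices$cell_id, degree = as.integer(counts))
}

#' Degree of one vertex
#'
#' @param g An `islet_graph`.
#' @param v A `cell_id` present in the graph.
#' @return Integer degree.
#' @export
degree_of <- function(g, v) {
  degs <- vertex_degrees(g)
  i <- match(v, degs$cell_id)
  if (is.na(i)) {
    abort("vertex not present in graph", class = "isletgraph_lookup_error")
  }
  degs$degree[i]
}

islet_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges[c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = g$vertices$cell_id)
  )
}

#' Graph measures of one islet graph
#'
#' Computes the three architecture measures: mean degree, number of connected
#' components (split into singular, i.e. lone beta cells, and nonsingular,
#' i.e. beta-cell clusters), and cells per component. Components are found by
#' graph traversal (igraph).
#'
#' @param g An `islet_graph`.
#' @return A one-row tibble with `n_vertices`, `n_edges`, `mean_degree`,
#'   `n_components`, `n_singular`, `n_nonsingular`, `cells_per_component`
#'   and `cells_per_nonsingular` (`NA` when the graph has no nonsingular
#'   component).
#' @export
islet_measures <- function(g) {
  stopifnot(inherits(g, "islet_graph"))
  n <- nrow(g$vertices)
  comp <- igraph::components(islet_igraph(g))
  sizes <- comp$csize
  n_sing <- sum(sizes == 1)
  n_nons <- sum(sizes > 1)
  tibble::tibble(
    n_vertices = n,
    n_edges = nrow(g$edges),
    mean_degree = 2 * nrow(g$edges) / n,
    n_components = length(sizes),
    n_singular = n_sing,
    n_nonsingular = n_nons,
    cells_per_component = n / length(sizes),
    cells_per_nonsingular = if (n_nons > 0) (n - n_sing) / n_nons else NA_real_
  )
}

#' Effective diameter of an islet
#'
#' Diameter of the circle with the same area as the islet's footprint:
#' `2 * sqrt(A / pi)`, where `A` is the convex-hull area of all endocrine
#' cell centres padded outward by one cell radius (Minkowski sum of the hull
#' with a disc). Islets whose centres are collinear or fewer than three use
#' the maximum pairwise extent plus one cell diameter instead.
#'
#' @param cells Tibble with `x`, `y` columns: all endocrine cells of one
#'   islet, not only beta cells.
#' @param cell_radius Cell radius in micrometres used for the padding.
#' @return Effective diameter in micrometres.
#' @export
effective_diameter <- function(cells, cell_radius = 4) {
  cells <- tibble::as_tibble(cells)
  stopifnot(nrow(cells) >= 1)
  xy <- unique(as.matrix(cells[c("x", "y")]))
  if (nrow(xy) < 3) {
    return(max(stats::dist(xy), 0) + 2 * cell_radius)
  }
  hull <- grDevices::chull(xy)
  hx <- xy[hull, 1]
  hy <- xy[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area < 1e-9) {  # collinear
    return(max(stats::dist(xy), 0) + 2 * cell_radius)
  }
  perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  area_padded <- area + perim * cell_radius + pi * cell_radius^2
  2 * sqrt(area_padded / pi)
}

#' Classify an islet as large or small
#'
#' Small islets are those with an [effective_diameter()] below the threshold
#' (60 micrometres by convention); the classification uses all endocrine
#' cells of the islet.
#'
#' @inheritParams effective_diameter
#' @param threshold Effective-diameter cut in micrometres.
#' @return `"large"` or `"small"`.
#' @export
classify_islet_size <- function(cells, threshold = 60, cell_radius = 4) {
  if (effective_diameter(cells, cell_radius) < threshold) "small" else "large"
}

#' Aggregate graph measures over a group of islets
#'
#' Degree is averaged over cells (every cell of the group contributes one
#' degree, matching the sum over all vertices of the dataset); component
#' counts are averaged per islet; cells per component is, by default,
#' averaged per component (total cells / total components), with a per-islet
#' mean available.
#'
#' @param measures A tibble of per-islet rows as returned by
#'   [islet_measures()] (possibly with extra grouping columns).
#' @param component_weighting `"per_component"` or `"per_islet"` for the
#'   cells-per-component averages.
#' @return A one-row tibble of aggregated measures.
#' @export
aggregate_measures <- function(measures,
                               component_weighting = c("per_component",
                                                       "per_islet")) {
  component_weighting <- match.arg(component_weighting)
  measures <- tibble::as_tibble(measures)
  if (nrow(measures) == 0) {
    abort("cannot aggregate an empty collection",
          class = "isletgraph_value_error")
  }
  n_cells <- sum(measures$n_vertices)
  out <- tibble::tibble(
    n_islets = nrow(measures),
    n_cells = n_cells,
    mean_degree = sum(measures$mean_degree * measures$n_vertices) / n_cells,
    n_components = mean(measures$n_components),
    n_singular = mean(measures$n_singular),
    n_nonsingular = mean(measures$n_nonsingular)
  )
  if (component_weighting == "per_component") {
    out$cells_per_component <-
      sum(measures$n_vertices) / sum(measures$n_components)
    nons <- dplyr::filter(measures, .data$n_nonsingular > 0)
    out$cells_per_nonsingular <- if (nrow(nons) > 0) {
      sum(nons$n_vertices - nons$n_singular) / sum(nons$n_nonsingular)
    } else NA_real_
  } else {
    out$cells_per_component <- mean(measures$cells_per_component)
    out$cells_per_nonsingular <-
      mean(measures$cells_per_nonsingular, na.rm = TRUE)
  }
  out
}

#' Measure graphs for every islet of a table, across radii
#'
#' Convenience sweep: builds graphs and computes per-islet measures for each
#' neighborhood radius.
#'
#' @param tbl A validated islet table (typically beta cells only).
#' @param radii Numeric vector of neighborhood radii in micrometres.
#' @param params Base [neighborhood_params()]; its radius is replaced by each
#'   element of `radii`.
#' @return A tibble with one row per (islet, radius) carrying the islet
#'   identifiers, `radius` and the measure columns.
#' @export
measure_islets <- function(tbl, radii = 10, params = neighborhood_params()) {
  purrr::map_dfr(radii, function(r) {
    p <- neighborhood_params(radius = r, cell_radius = params$cell_radius,
                             symmetrize = params$symmetrize)
    build_islet_graphs(tbl, p) |>
      dplyr::mutate(radius = r,
                    measures = purrr::map(.data$graph, islet_measures)) |>
      dplyr::select(-"graph") |>
      tidyr::unnest("measures")
  })
}

#' Compare a measure between two groups of islets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of per-islet measure
#' values between two groups, with a Bonferroni multiple-comparison
#' threshold: significance requires `p < 0.05 / n_tests`. Degree comparisons
#' across the radius sweep use `n_tests = 32`, component comparisons 64.
#'
#' @param a,b Numeric vectors of per-islet measure values.
#' @param n_tests Number of comparisons in the family.
#' @param alpha Family-wise error rate before division.
#' @return A one-row tibble with `statistic`, `p_value`, `threshold` and
#'   `significant`.
#' @export
compare_groups <- function(a, b, n_tests = 1, alpha = 0.05) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) {
    warn("all values tied across both samples; p set to 1")
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          threshold = alpha / n_tests, significant = FALSE))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- min(ht$p.value, 1)
  tibble::tibble(statistic = unname(ht$statistic), p_value = p,
                 threshold = alpha / n_tests,
                 significant = p < alpha / n_tests)
}
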