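#' Relative-likelihood kernel
#'
#' Sigmoidal weights controlling which vertices are favoured for theoretical
#' addition (as parents) or deletion: `RL+ = 0.5 + 0.5 tanh(x - rlp)`
#' (direction `"P"`, increasing in the basis quantity `x`) and
#' `RL- = 0.5 - 0.5 tanh(x - rlp)` (direction `"M"`, decreasing), where `x`
#' is the vertex's degree or the size of its component and `rlp` is the
#' sigmoid midpoint in the same units. The two directions are complementary:
#' `RL+ + RL- = 1` for every `x`.
#'
#' @param x Basis quantity (degree or component size); vectorised.
#' @param direction `"P"` (RL+) or `"M"` (RL-).
#' @param rlp Midpoint parameter. Degree-based sweeps use 0-7, component
#'   based sweeps 1-5.
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' rl_value(0:5, "M", rlp = 2)
rl_value <- function(x, direction = c("P", "M"), rlp) {
  direction <- match.arg(direction)
  s <- if (direction == "P") 1 else -1
  0.5 + s * 0.5 * tanh(x - rlp)
}

#' Stochastic model specification
#'
#' A model is a pair of relative-likelihood kernels, one for the addition
#' step and one for the deletion step, on a common basis (degree or
#' component size). The shorthand code is
#' `[dir_a][dir_d][rlp_a][rlp_d]`: `"MP01"` means addition uses RL- with
#' `rlp_a = 0` and deletion uses RL+ with `rlp_d = 1`.
#'
#' @param code Four-character shorthand, or `NULL` when the pieces are given
#'   explicitly.
#' @param add_dir,del_dir `"P"` or `"M"`.
#' @param rlp_a,rlp_d Midpoints of the addition and deletion kernels.
#' @param basis `"degree"` or `"component"`.
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec("MP01", basis = "component")
model_spec <- function(code = NULL, add_dir = NULL, del_dir = NULL,
                       rlp_a = NULL, rlp_d = NULL,
                       basis = c("degree", "component")) {
  basis <- match.arg(basis)
  if (!is.null(code)) {
    stopifnot(nchar(code) == 4)
    add_dir <- substr(code, 1, 1)
    del_dir <- substr(code, 2, 2)
    rlp_a <- as.numeric(substr(code, 3, 3))
    rlp_d <- as.numeric(substr(code, 4, 4))
  }
  stopifnot(add_dir %in% c("P", "M"), del_dir %in% c("P", "M"),
            is.numeric(rlp_a), is.numeric(rlp_d))
  structure(
    list(add_dir = add_dir, del_dir = del_dir,
         rlp_a = rlp_a, rlp_d = rlp_d, basis = basis,
         code = paste0(add_dir, del_dir, rlp_a, rlp_d)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s-based): add RL%s rlp=%g, delete RL%s rlp=%g\n",
              x$code, x$basis, if (x$add_dir == "P") "+" else "-", x$rlp_a,
              if (x$del_dir == "P") "+" else "-", x$rlp_d))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_iterations Deletion+addition iterations per replicate (full-scale
#'   studies use 500; desk-scale sweeps here default to 100).
#' @param n_replicates Independent replicates per model.
#' @param params [neighborhood_params()] used to rebuild the contact graph
#'   after every move.
#' @param placement_range New cells are placed at a uniform random distance
#'   in this range (um) from the parent.
#' @param d_min_fallback Minimum spacing used for islets with fewer than two
#'   cells (default 8 um: two touching 4 um cells).
#' @param trajectory Record measures at every iteration (`TRUE`) or only the
#'   final state?
#' @param max_wave Cycle guard on the relocation wave.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_iterations = 100, n_replicates = 20,
                       params = neighborhood_params(radius = 10),
                       placement_range = c(8, 13), d_min_fallback = 8,
                       trajectory = FALSE, max_wave = 100000) {
  stopifnot(n_iterations >= 1, n_replicates >= 1,
            length(placement_range) == 2,
            placement_range[1] < placement_range[2])
  structure(
    list(n_iterations = n_iterations, n_replicates = n_replicates,
         params = params, placement_range = placement_range,
         d_min_fallback = d_min_fallback, trajectory = trajectory,
         max_wave = max_wave),
    class = "sim_config"
  )
}

# d_min rule: the minimal centre-to-centre distance observed in the islet,
# capped at the two-touching-cells distance (placement draws from [8,13] um
# presume contacts at >= 8 um), with the fallback for singleton islets.
islet_d_min <- function(cells, config) {
  if (nrow(cells) < 2) return(config$d_min_fallback)
  min(cpp_min_pairdist(as.matrix(cells[c("x", "y")])), config$d_min_fallback)
}

#' Select a vertex under a relative-likelihood kernel
#'
#' Draws one vertex with probability proportional to its relative likelihood
#' `rl_value(x_v)`, where `x_v` is the vertex's degree or component size.
#'
#' @param g An `islet_graph`.
#' @param direction,rlp Kernel direction and midpoint (see [rl_value()]).
#' @param basis `"degree"` or `"component"`.
#' @return The selected `cell_id`.
#' @export
select_vertex <- function(g, direction, rlp,
                          basis = c("degree", "component")) {
  basis <- match.arg(basis)
  if (nrow(g$vertices) == 0) {
    abort("cannot select from an empty graph",
          class = "isletgraph_value_error")
  }
  x <- if (basis == "degree") {
    vertex_degrees(g)$degree
  } else {
    comp <- igraph::components(islet_igraph(g))
    comp$csize[comp$membership]
  }
  w <- rl_value(x, direction, rlp)
  if (sum(w) <= 0) w <- rep(1, length(w))
  g$vertices$cell_id[sample.int(length(w), 1, prob = w)]
}

#' Steric vertex addition next to a parent cell
#'
#' Places a new cell at a uniform random distance in `placement_range` from
#' the parent, at an angle drawn uniformly from the directions not occupied
#' by a neighbour of the parent (the complement of the union of each
#' neighbour's shadow interval). Crowding is then resolved by the
#' frozen/problem relocation wave: cells within `d_min` of the newcomer are
#' pushed radially outward from the parent until their clearance to the
#' nearest frozen cell lies in `[d_min, 10]` um, recursively, until no
#' violation remains.
#'
#' @param g An `islet_graph` (2d).
#' @param parent `cell_id` of the parent vertex.
#' @param d_min Minimum spacing to enforce; default, the islet's observed
#'   minimum (capped at 8 um).
#' @param config A [sim_config()].
#' @return An `islet_graph` with one more vertex (the newcomer gets the next
#'   free `cell_id`), rebuilt at the same neighborhood parameters.
#' @export
add_vertex <- function(g, parent, d_min = NULL, config = sim_config()) {
  stopifnot(inherits(g, "islet_graph"))
  d_min <- d_min %||% islet_d_min(g$vertices, config)
  idx <- match(parent, g$vertices$cell_id)
  if (is.na(idx)) {
    abort("parent vertex not found", class = "isletgraph_lookup_error")
  }
  res <- cpp_add_vertex(
    as.matrix(g$vertices[c("x", "y")]), idx,
    g$params$radius, g$params$cell_radius,
    g$params$symmetrize == "mutual", d_min,
    config$placement_range[1], config$placement_range[2], config$max_wave
  )
  new_cells <- tibble::tibble(
    cell_id = c(g$vertices$cell_id, max(g$vertices$cell_id) + 1L),
    x = res$coords[, 1], y = res$coords[, 2]
  )
  build_islet_graph(new_cells, g$params)
}

#' Run the balanced rearrangement process on a cohort
#'
#' For every islet (with at least two cells of interest) and every
#' replicate: per iteration, one vertex is deleted (selected under the
#' deletion kernel) and one vertex is added next to a parent (selected under
#' the addition kernel) with steric relocation, the contact graph being
#' recomputed after every move. Cell number per islet is conserved at every
#' iteration by construction. Driven by the R random number stream: set a
#' seed first for bit-reproducible runs.
#'
#' @param tbl A validated islet table already reduced to the vertex cell
#'   type (e.g. via [filter_cells()]); islets with fewer than 2 cells are
#'   skipped and counted in the `n_skipped_islets` attribute.
#' @param model A [model_spec()].
#' @param config A [sim_config()].
#' @return A tibble of class `islet_sim` with one row per
#'   (islet, replicate, recorded iteration): identifiers, `iteration`,
#'   `n_vertices`, `mean_degree`, `n_components`, `n_singular`,
#'   `cells_per_component`, `min_pairdist` and `d_min`.
#' @export
run_simulation <- function(tbl, model, config = sim_config()) {
  tbl <- tibble::as_tibble(tbl)
  islets <- dplyr::group_split(tbl, .data$group, .data$subject_id,
                               .data$islet_id)
  runnable <- vapply(islets, nrow, integer(1)) >= 2
  n_skipped <- sum(!runnable)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " islet(s) with < 2 cells skipped"))
  }
  islets <- islets[runnable]
  if (length(islets) == 0) {
    abort("no islet with at least 2 cells", class = "isletgraph_value_error")
  }
  add_dir <- if (model$add_dir == "P") 1L else -1L
  del_dir <- if (model$del_dir == "P") 1L else -1L
  basis <- if (model$basis == "degree") 0L else 1L
  out <- purrr::map_dfr(islets, function(ic) {
    coords <- as.matrix(ic[c("x", "y")])
    d_min <- islet_d_min(ic, config)
    purrr::map_dfr(seq_len(config$n_replicates), function(rep) {
      sim <- cpp_simulate_islet(
        coords, config$params$radius, config$params$cell_radius,
        config$params$symmetrize == "mutual",
        add_dir, model$rlp_a, del_dir, model$rlp_d,
        basis, config$n_iterations,
        config$placement_range[1], config$placement_range[2], d_min,
        config$trajectory, config$max_wave
      )
      m <- tibble::as_tibble(sim$measures)
      m$replicate <- rep
      m
    }) |>
      dplyr::mutate(group = ic$group[1], subject_id = ic$subject_id[1],
                    islet_id = ic$islet_id[1], d_min = d_min)
  })
  out <- dplyr::relocate(out, "group", "subject_id", "islet_id", "replicate")
  attr(out, "model") <- model
  attr(out, "config") <- config
  attr(out, "n_skipped_islets") <- n_skipped
  class(out) <- c("islet_sim", class(out))
  out
}

#' Sweep a family of models over an rlp grid
#'
#' Runs [run_simulation()] for every `(rlp_a, rlp_d)` combination of a model
#' family (e.g. `"MP"`) and summarises each combination by its
#' replicate-mean final measures, aggregated over islets.
#'
#' @param tbl Vertex-type islet table.
#' @param family Two-letter family code (`[dir_a][dir_d]`, e.g. `"MP"`).
#' @param basis `"degree"` or `"component"`.
#' @param rlp_a_grid,rlp_d_grid Midpoint grids. Degree sweeps conventionally
#'   use 0-7, component sweeps 1-5.
#' @param config A [sim_config()].
#' @return A tibble with one row per (rlp_a, rlp_d, replicate):
#'   islet-aggregated `mean_degree`, `n_components` (per islet) and
#'   `cells_per_component`.
#' @export
sweep_models <- function(tbl, family = "MP",
                         basis = c("component", "degree"),
                         rlp_a_grid = 1:5, rlp_d_grid = 1:5,
                         config = sim_config()) {
  basis <- match.arg(basis)
  grid <- tidyr::expand_grid(rlp_a = rlp_a_grid, rlp_d = rlp_d_grid)
  purrr::pmap_dfr(grid, function(rlp_a, rlp_d) {
    model <- model_spec(add_dir = substr(family, 1, 1),
                        del_dir = substr(family, 2, 2),
                        rlp_a = rlp_a, rlp_d = rlp_d, basis = basis)
    sim <- run_simulation(tbl, model, config)
    sim |>
      dplyr::filter(.data$iteration == max(.data$iteration)) |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(
        mean_degree = sum(.data$mean_degree * .data$n_vertices) /
          sum(.data$n_vertices),
        cells_per_component = sum(.data$n_vertices) /
          sum(.data$n_components),
        n_components = mean(.data$n_components),
        .groups = "drop"
      ) |>
      dplyr::mutate(family = family, basis = basis,
                    rlp_a = rlp_a, rlp_d = rlp_d, .before = 1)
  })
}

#' Convergence diagnostics over accumulating replicates
#'
#' For each replicate count `i`, the standard deviation over replicates
#' `1..i` of each measure is computed per `(rlp_a, rlp_d)` combination and
#' maximised over combinations; likewise the absolute change in the running
#' mean when replicate `i` is added. Convergence shows as the maximal SD
#' flattening and the maximal change in mean approaching zero.
#'
#' @param sweep A tibble as returned by [sweep_models()] (needs `replicate`,
#'   `rlp_a`, `rlp_d` and measure columns).
#' @param measures Character vector of measure columns to diagnose.
#' @return A tibble with `i`, `measure`, `max_sd`, `max_dmean`.
#' @export
convergence_diagnostics <- function(sweep,
                                    measures = c("mean_degree",
                                                 "n_components",
                                                 "cells_per_component")) {
  sweep <- tibble::as_tibble(sweep)
  stopifnot(all(c("replicate", "rlp_a", "rlp_d") %in% names(sweep)),
            max(sweep$replicate) >= 2)
  long <- sweep |>
    dplyr::select(dplyr::all_of(c("rlp_a", "rlp_d", "replicate", measures))) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure") |>
    dplyr::arrange(.data$rlp_a, .data$rlp_d, .data$measure, .data$replicate)
  purrr::map_dfr(sort(unique(long$replicate)), function(i) {
    upto <- dplyr::filter(long, .data$replicate <= i)
    per <- upto |>
      dplyr::group_by(.data$rlp_a, .data$rlp_d, .data$measure) |>
      dplyr::summarise(
        sd_i = if (i >= 2) sd(.data$value) else NA_real_,
        dmean_i = if (i >= 2) {
          abs(mean(.data$value) -
                mean(.data$value[.data$replicate < i]))
        } else NA_real_,
        .groups = "drop"
      )
    per |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(max_sd = max(.data$sd_i),
                       max_dmean = max(.data$dmean_i), .groups = "drop") |>
      dplyr::mutate(i = i, .before = 1)
  })
}
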