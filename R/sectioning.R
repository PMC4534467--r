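#' Jitter z coordinates under a global minimum spacing
#'
#' Perturbs each cell's z by an independent uniform draw in
#' `[-half_width, half_width]`; a draw that would bring the cell within
#' `min_distance` of any other cell (at its current position) is rejected
#' and redrawn, per cell, up to `max_retries` times. Used to turn a stack of
#' discrete 15 um slices into a plausible continuous 3d volume before
#' re-sectioning it.
#'
#' @param cells 3d cell records (with `z`); minimum pairwise distance at
#'   least `min_distance` already.
#' @param half_width Jitter half-width in micrometres (default 7.5, half a
#'   slice).
#' @param min_distance Global minimum spacing to preserve (default 4 um).
#' @param max_retries Per-cell retry budget before erroring.
#' @return The table with jittered `z`; minimum pairwise distance is still
#'   at least `min_distance`.
#' @export
perturb_z <- function(cells, half_width = 7.5, min_distance = 4,
                      max_retries = 1000) {
  cells <- tibble::as_tibble(cells)
  stopifnot("z" %in% names(cells))
  n <- nrow(cells)
  x <- cells$x
  y <- cells$y
  z <- cells$z
  for (i in seq_len(n)) {
    ok <- n == 1
    for (try in seq_len(max_retries)) {
      if (ok) break
      cand <- cells$z[i] + runif(1, -half_width, half_width)
      d2 <- (x[-i] - x[i])^2 + (y[-i] - y[i])^2 + (z[-i] - cand)^2
      if (min(d2) >= min_distance^2) {
        z[i] <- cand
        ok <- TRUE
      }
    }
    if (!ok) {
      abort(paste0("could not jitter cell ", cells$cell_id[i],
                   " without violating the ", min_distance,
                   " um minimum distance"),
            class = "isletgraph_geometry_error")
    }
  }
  cells$z <- z
  cells
}

#' Slice a 3d volume into 2d sections
#'
#' Partitions cells into slabs of the given thickness with respect to z:
#' section `k` holds cells with `z` in
#' `[slice_start + k * thickness, slice_start + (k + 1) * thickness)`
#' (half-open, so every cell lands in exactly one section).
#'
#' @param cells 3d cell records.
#' @param thickness Slab thickness in micrometres (default 15).
#' @param slice_start Offset of the first cut in micrometres, in
#'   `[0, thickness)`.
#' @return The table with an integer `section` column; `z` is retained for
#'   bookkeeping but sections are meant to be analysed via `(x, y)` only.
#' @export
slice_volume <- function(cells, thickness = 15, slice_start = 0) {
  stopifnot(slice_start >= 0, slice_start < thickness)
  cells <- tibble::as_tibble(cells)
  stopifnot("z" %in% names(cells))
  dplyr::mutate(cells,
                section = as.integer(floor((.data$z - slice_start) /
                                             thickness)))
}

#' Compare graph measures between a 3d volume and its 2d sections
#'
#' For each neighborhood radius, computes islet-aggregated measures on the
#' full 3d volume (neighborhood-sphere graphs) and on the 2d section graphs
#' for every slice start. Sections inherit the islet's identity; each
#' (islet, section) with at least one cell forms one 2d graph.
#'
#' @param volume 3d cell records (one or more islets, vertex type already
#'   selected).
#' @param radii Neighborhood radii to sweep (micrometres).
#' @param slice_starts Integer offsets of the slicing origin.
#' @param thickness Slab thickness (micrometres).
#' @param params Base [neighborhood_params()] (radius replaced per sweep).
#' @return A tibble with `radius`, `geometry` (`"3d"` or `"2d"`),
#'   `slice_start` (`NA` for 3d) and aggregated measure columns.
#' @export
compare_2d_3d <- function(volume, radii = 8:13, slice_starts = 0:14,
                          thickness = 15, params = neighborhood_params()) {
  volume <- tibble::as_tibble(volume)
  measure_at <- function(tbl, radius, drop_z) {
    p <- neighborhood_params(radius = radius,
                             cell_radius = params$cell_radius,
                             symmetrize = params$symmetrize)
    if (drop_z) tbl <- dplyr::select(tbl, -"z")
    per <- tbl |>
      dplyr::group_by(.data$subject_id, .data$islet_id) |>
      dplyr::group_map(~ islet_measures(build_islet_graph(.x, p))) |>
      dplyr::bind_rows()
    aggregate_measures(per)
  }
  purrr::map_dfr(radii, function(r) {
    three_d <- measure_at(volume, r, drop_z = FALSE) |>
      dplyr::mutate(radius = r, geometry = "3d", slice_start = NA_integer_,
                    .before = 1)
    two_d <- purrr::map_dfr(slice_starts, function(s0) {
      sliced <- slice_volume(volume, thickness, s0) |>
        dplyr::mutate(islet_id = .data$islet_id * 10000L + .data$section +
                        5000L)  # one 2d graph per (islet, section)
      measure_at(sliced, r, drop_z = TRUE) |>
        dplyr::mutate(radius = r, geometry = "2d", slice_start = s0,
                      .before = 1)
    })
    dplyr::bind_rows(three_d, two_d)
  })
}
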