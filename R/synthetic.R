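#' Specification for a synthetic islet cohort
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a hard-core minimum spacing between cell centres (cells have a 4 um
#' radius, default hard core 8 um = two touching cells), short-range
#' aggregation around cluster seeds tuned so the same-type pair distribution
#' peaks in the 8-13 um contact band, an islet size mixture spanning small
#' (< 60 um effective diameter) and large islets, and endocrine type
#' fractions near those observed in control cohorts (~56% beta).
#'
#' @param n_islets Number of islets in the cohort.
#' @param p_large Probability an islet is drawn from the large-islet size
#'   class (control cohorts run near 0.32).
#' @param cells_small,cells_large Inclusive cell-count ranges for small and
#'   large islets; counts are drawn uniformly.
#' @param fractions Named numeric (alpha, beta, delta) type fractions
#'   summing to 1.
#' @param hard_core Minimum centre-to-centre spacing in micrometres; must be
#'   at least one cell diameter.
#' @param cells_per_cluster Target number of cells per aggregation seed.
#' @param cluster_sd Spread (um) of cells around their seed; together with
#'   the hard core this sets the location of the pair-distribution peak.
#' @param cell_radius Cell radius in micrometres.
#' @param max_tries Dart-throwing retry budget per cell.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_islets = 200, p_large = 0.32,
                        cells_small = c(3, 12), cells_large = c(25, 90),
                        fractions = c(alpha = 0.33, beta = 0.56,
                                      delta = 0.11),
                        hard_core = 8, cells_per_cluster = 6,
                        cluster_sd = 8, cell_radius = 4, max_tries = 2000) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, hard_core >= 2 * cell_radius,
            n_islets >= 1, p_large >= 0, p_large <= 1)
  structure(
    list(n_islets = n_islets, p_large = p_large, cells_small = cells_small,
         cells_large = cells_large, fractions = fractions,
         hard_core = hard_core, cells_per_cluster = cells_per_cluster,
         cluster_sd = cluster_sd, cell_radius = cell_radius,
         max_tries = max_tries),
    class = "cohort_spec"
  )
}

# Dart-throwing hard-core placement around cluster seeds inside a disc of
# radius `region_r`. Exact constraint satisfaction; errors out when the
# requested density is infeasible within the retry budget.
place_hardcore <- function(n, region_r, spec) {
  n_seeds <- max(1L, round(n / spec$cells_per_cluster))
  ru <- region_r * sqrt(runif(n_seeds))
  th <- runif(n_seeds, 0, 2 * pi)
  seeds <- cbind(ru * cos(th), ru * sin(th))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(spec$max_tries)) {
      s <- seeds[sample.int(n_seeds, 1), ]
      # widen the spread as rejections accumulate so locally saturated
      # clusters spill over instead of jamming the whole placement
      sd_eff <- spec$cluster_sd * (1 + 2 * try / spec$max_tries)
      cand <- s + stats::rnorm(2, sd = sd_eff)
      if (sum(cand^2) > (region_r + 3 * spec$cluster_sd)^2) next
      if (placed > 0) {
        d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
          (pts[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < spec$hard_core^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(paste0("dart-throwing failed to place ", n, " cells with an ",
                   spec$hard_core, " um hard core in a disc of radius ",
                   region_r, " um; request fewer cells"),
            class = "isletgraph_generation_error")
    }
  }
  pts
}

#' Generate one synthetic islet
#'
#' Cluster-seeded hard-core point process: seeds are placed uniformly in a
#' disc whose radius scales with the requested cell count, cells are placed
#' around random seeds by dart throwing with the hard-core constraint, and
#' types are assigned independently from the fraction vector.
#'
#' @param n_cells Number of cells; when `NULL`, drawn from the size class.
#' @param spec A [cohort_spec()].
#' @param size `"small"` or `"large"`; sets the count range and disc radius
#'   when `n_cells` is `NULL`.
#' @param subject_id,islet_id Identifier columns for the output records.
#' @param group Cohort label attached to the records.
#' @return A tibble of cell records for one islet (passes
#'   [validate_islet_table()]).
#' @export
generate_islet <- function(n_cells = NULL, spec = cohort_spec(),
                           size = c("small", "large"),
                           subject_id = "S1", islet_id = 1L,
                           group = "control") {
  size <- match.arg(size)
  if (is.null(n_cells)) {
    rng <- if (size == "small") spec$cells_small else spec$cells_large
    n_cells <- sample(seq(rng[1], rng[2]), 1)
  }
  # area per cell ~2.7x the hard-core disc keeps dart throwing feasible
  region_r <- if (size == "small") {
    min(18, 3 + 4.5 * sqrt(n_cells))
  } else {
    max(35, 6.5 * sqrt(n_cells))
  }
  pts <- place_hardcore(n_cells, region_r, spec)
  types <- sample(names(spec$fractions), n_cells, replace = TRUE,
                  prob = spec$fractions)
  tibble::tibble(
    subject_id = subject_id, group = group,
    islet_id = as.integer(islet_id), cell_id = seq_len(n_cells),
    x = pts[, 1], y = pts[, 2], cell_type = types
  )
}

#' Generate a synthetic islet cohort
#'
#' Mixes small and large islets per the size distribution of the spec. Uses
#' the R random number stream: call `set.seed()` first for reproducible
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id,group Identifiers attached to all islets.
#' @return A validated islet table.
#' @export
#' @examples
#' set.seed(1)
#' tbl <- generate_cohort(cohort_spec(n_islets = 5))
generate_cohort <- function(spec = cohort_spec(), subject_id = "S1",
                            group = "control") {
  sizes <- ifelse(runif(spec$n_islets) < spec$p_large, "large", "small")
  tbl <- purrr::map_dfr(seq_len(spec$n_islets), function(i) {
    generate_islet(spec = spec, size = sizes[i], subject_id = subject_id,
                   islet_id = i, group = group)
  })
  validate_islet_table(tbl)
}

#' Generate a synthetic 3d islet volume
#'
#' Places cells in a ball with the same dart-throwing hard-core rule (and a
#' global minimum spacing of at least 4 um, the cell radius constraint used
#' when jittering z), for testing the sectioning pipeline.
#'
#' @param n_cells Number of cells.
#' @param spec A [cohort_spec()]; `hard_core` applies in 3d.
#' @param radius_um Ball radius; `NULL` scales with the cell count.
#' @param subject_id,islet_id,group Identifier columns.
#' @return A tibble of 3d cell records (with a `z` column).
#' @export
generate_volume <- function(n_cells = 200, spec = cohort_spec(),
                            radius_um = NULL, subject_id = "V1",
                            islet_id = 1L, group = "control") {
  region_r <- radius_um %||% max(25, 5.2 * n_cells^(1 / 3) * 2)
  pts <- matrix(NA_real_, n_cells, 3)
  placed <- 0L
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(spec$max_tries)) {
      cand <- stats::rnorm(3)
      cand <- cand / sqrt(sum(cand^2)) * region_r * runif(1)^(1 / 3)
      if (placed > 0) {
        d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < spec$hard_core^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      abort("dart-throwing failed in 3d; request fewer cells or a larger ball",
            class = "isletgraph_generation_error")
    }
  }
  types <- sample(names(spec$fractions), n_cells, replace = TRUE,
                  prob = spec$fractions)
  tibble::tibble(
    subject_id = subject_id, group = group,
    islet_id = as.integer(islet_id), cell_id = seq_len(n_cells),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], cell_type = types
  )
}
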