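#' Pair distribution function of one islet
#'
#' Estimates the radial pair distribution g(r): the density of cell pairs at
#' centre-to-centre distance r relative to the uniform expectation, so that
#' g is identically 1 under complete spatial randomness. For one cell type,
#' for each distance bin of width `dr` centred at `r`,
#' `g(r) = Area / (2 pi r N^2) * (# ordered pairs with distance in bin) / dr`;
#' for two disjoint types a and b the ordered pairs run a to b only and the
#' normalisation is `N_a * N_b`. `Area` is the axis-aligned bounding box of
#' the cells entering the estimate. No boundary (edge) correction is applied,
#' which biases the estimate low at distances comparable to the islet extent.
#'
#' @param cells_a Tibble with `x`, `y` columns (one islet, one cell type).
#' @param cells_b Optional second type for the cross-type estimate.
#' @param breaks Bin edges in micrometres (default 0-50 um, 1 um bins).
#' @param area Override for the normalising area (um^2); default bounding
#'   box of the cells used.
#' @return A tibble of class `islet_pairdist` with `r` (bin centre), `r_lo`,
#'   `r_hi`, `n_pairs` (ordered pairs) and `g`; attributes `area`, `n_a`,
#'   `n_b`. When fewer than 2 cells enter or the bounding box is degenerate,
#'   `g` is `NA` everywhere and a warning is raised.
#' @export
pair_distribution <- function(cells_a, cells_b = NULL,
                              breaks = seq(0, 50, by = 1), area = NULL) {
  cells_a <- tibble::as_tibble(cells_a)
  cross <- !is.null(cells_b)
  if (cross) cells_b <- tibble::as_tibble(cells_b)
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  all_xy <- if (cross) {
    rbind(as.matrix(cells_a[c("x", "y")]), as.matrix(cells_b[c("x", "y")]))
  } else {
    as.matrix(cells_a[c("x", "y")])
  }
  n_a <- nrow(cells_a)
  n_b <- if (cross) nrow(cells_b) else n_a
  box_area <- area %||%
    ((max(all_xy[, 1]) - min(all_xy[, 1])) *
       (max(all_xy[, 2]) - min(all_xy[, 2])))
  skeleton <- tibble::tibble(
    r_lo = head(breaks, -1), r_hi = tail(breaks, -1),
    r = (head(breaks, -1) + tail(breaks, -1)) / 2
  )
  bad <- if (cross) (n_a < 1 || n_b < 1) else n_a < 2
  if (bad || !is.finite(box_area) || box_area <= 0) {
    warn("pair distribution undefined: fewer than 2 cells or degenerate bounding box")
    out <- dplyr::mutate(skeleton, n_pairs = NA_integer_, g = NA_real_)
    return(new_pairdist(out, box_area, n_a, n_b))
  }
  bin_counts <- function(d) {  # half-open [lo, hi) bins
    d <- d[d >= breaks[1] & d < breaks[length(breaks)]]
    tabulate(findInterval(d, breaks), nbins = length(breaks) - 1)
  }
  if (cross) {
    d2 <- outer(cells_a$x, cells_b$x, "-")^2 + outer(cells_a$y, cells_b$y, "-")^2
    n_ordered <- bin_counts(sqrt(as.vector(d2)))
    norm <- n_a * n_b
  } else {
    dists <- as.vector(stats::dist(as.matrix(cells_a[c("x", "y")])))
    n_ordered <- 2L * bin_counts(dists)
    norm <- n_a^2
  }
  dr <- skeleton$r_hi - skeleton$r_lo
  out <- dplyr::mutate(
    skeleton,
    n_pairs = n_ordered,
    g = box_area / (2 * pi * .data$r * norm) * .data$n_pairs / dr
  )
  new_pairdist(out, box_area, n_a, n_b)
}

new_pairdist <- function(tbl, area, n_a, n_b) {
  structure(tbl, area = area, n_a = n_a, n_b = n_b,
            class = c("islet_pairdist", class(tbl)))
}

#' Average pair distributions over islets
#'
#' Unweighted per-bin mean of g over the islets contributing a defined
#' estimate at that bin (islets whose estimate is undefined are skipped).
#'
#' @param pds A list of `islet_pairdist` objects sharing the same bins.
#' @return An `islet_pairdist` whose `g` is the per-bin mean and whose
#'   `n_islets` column counts contributors.
#' @export
average_pair_distributions <- function(pds) {
  stopifnot(length(pds) >= 1)
  r0 <- pds[[1]]$r
  for (p in pds) {
    if (!isTRUE(all.equal(p$r, r0))) {
      abort("pair distributions must share the same bins",
            class = "isletgraph_value_error")
    }
  }
  gmat <- vapply(pds, function(p) p$g, numeric(length(r0)))
  gmat <- matrix(gmat, nrow = length(r0))
  n_ok <- rowSums(!is.na(gmat))
  gbar <- rowMeans(gmat, na.rm = TRUE)
  gbar[n_ok == 0] <- NA_real_
  out <- tibble::tibble(
    r_lo = pds[[1]]$r_lo, r_hi = pds[[1]]$r_hi, r = r0,
    g = gbar, n_islets = n_ok
  )
  new_pairdist(out, NA_real_, NA_integer_, NA_integer_)
}

#' Difference between two pair distributions
#'
#' Per-bin difference `g1 - g2` and the integrated absolute difference
#' over a radius window, by the rectangle rule on the shared bins. Both the
#' full window (default 0-50 um) and the non-random contact band (8-13 um)
#' are reported.
#'
#' @param g1,g2 `islet_pairdist` objects on the same bins.
#' @param r_lo,r_hi Integration window in micrometres.
#' @param band Secondary window of interest (default `c(8, 13)`).
#' @return A list of class `pairdist_difference` with `bins` (tibble of `r`
#'   and `difference`), `integral` and `band_integral`.
#' @export
pairdist_difference <- function(g1, g2, r_lo = 0, r_hi = 50,
                                band = c(8, 13)) {
  if (!isTRUE(all.equal(g1$r, g2$r))) {
    abort("pair distributions must share the same bins",
          class = "isletgraph_value_error")
  }
  bins <- tibble::tibble(
    r_lo = g1$r_lo, r_hi = g1$r_hi, r = g1$r,
    difference = g1$g - g2$g
  )
  rect <- function(lo, hi) {
    sel <- bins$r_lo >= lo & bins$r_hi <= hi
    sum(abs(bins$difference[sel]) * (bins$r_hi[sel] - bins$r_lo[sel]),
        na.rm = TRUE)
  }
  structure(
    list(bins = bins, integral = rect(r_lo, r_hi),
         band_integral = rect(band[1], band[2])),
    class = "pairdist_difference"
  )
}

#' @export
print.pairdist_difference <- function(x, ...) {
  cat(sprintf(
    "<pairdist_difference> integral |g1-g2| dr = %.4g (band: %.4g)\n",
    x$integral, x$band_integral))
  invisible(x)
}

#' Averaged beta-beta pair distribution of a cohort
#'
#' Runs [pair_distribution()] on the chosen cell type of every islet (islets
#' with fewer than two such cells are skipped) and averages per bin.
#'
#' @param tbl A validated islet table.
#' @param cell_type Cell type whose same-type distribution is wanted.
#' @param size_class Optional `"large"`/`"small"` restriction, classified on
#'   all endocrine cells of each islet.
#' @param breaks Bin edges in micrometres.
#' @return An `islet_pairdist` averaged over islets.
#' @export
cohort_pair_distribution <- function(tbl, cell_type = "beta",
                                     size_class = NULL,
                                     breaks = seq(0, 50, by = 1)) {
  tbl <- tibble::as_tibble(tbl)
  islets <- dplyr::group_split(tbl, .data$group, .data$subject_id,
                               .data$islet_id)
  if (!is.null(size_class)) {
    keep <- vapply(islets, function(ic) {
      classify_islet_size(ic) == size_class
    }, logical(1))
    islets <- islets[keep]
  }
  pds <- purrr::map(islets, function(ic) {
    sub <- dplyr::filter(ic, .data$cell_type == !!cell_type)
    if (nrow(sub) < 2) return(NULL)
    suppressWarnings(pair_distribution(sub, breaks = breaks))
  })
  pds <- purrr::compact(pds)
  if (length(pds) == 0) {
    abort("no islet with at least two cells of the requested type",
          class = "isletgraph_value_error")
  }
  average_pair_distributions(pds)
}
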