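#' Simulated-minus-experimental measure differences
#'
#' @param sim,exp One-row tibbles of aggregated measures (same radius,
#'   group and size class), e.g. from [aggregate_measures()].
#' @param measures Columns to difference.
#' @return A tibble with `measure` and `difference` (simulated minus
#'   experimental).
#' @export
measure_difference <- function(sim, exp,
                               measures = c("mean_degree", "n_components",
                                            "cells_per_component")) {
  missing <- setdiff(measures, intersect(names(sim), names(exp)))
  if (length(missing) > 0) {
    abort(paste0("measure column(s) absent from one side: ",
                 paste(missing, collapse = ", ")),
          class = "isletgraph_value_error")
  }
  tibble::tibble(
    measure = measures,
    difference = unname(vapply(measures, function(m) sim[[m]][1] - exp[[m]][1],
                               numeric(1)))
  )
}

#' Difference curves of a model sweep against experimental measures
#'
#' Averages a [sweep_models()] result over replicates and subtracts the
#' experimental (original-architecture) aggregated measures, yielding one
#' difference curve in `rlp_d` per (measure, rlp_a).
#'
#' @param sweep Output of [sweep_models()].
#' @param exp One-row tibble of experimental aggregated measures.
#' @param measures Measure columns shared by both.
#' @return A tibble with `family`, `basis`, `measure`, `rlp_a`, `rlp_d`,
#'   `difference`.
#' @export
difference_curves <- function(sweep, exp,
                              measures = c("mean_degree", "n_components",
                                           "cells_per_component")) {
  sweep |>
    dplyr::group_by(.data$family, .data$basis, .data$rlp_a, .data$rlp_d) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(measures), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "simulated") |>
    dplyr::mutate(difference = .data$simulated -
                    purrr::map_dbl(.data$measure, ~ exp[[.x]][1])) |>
    dplyr::arrange(.data$measure, .data$rlp_a, .data$rlp_d)
}

#' X-intercepts of a quadratic fit to a difference curve
#'
#' Fits `y = a x^2 + b x + c` by ordinary least squares to the
#' `(rlp_d, difference)` points of one curve and returns the real roots that
#' fall inside the swept `rlp_d` range. With three points the fit
#' interpolates exactly; a vanishing quadratic coefficient degrades
#' gracefully to the linear root, and a fully degenerate fit returns no
#' roots with a flag.
#'
#' @param rlp_d Sweep positions (at least 3).
#' @param difference Mean simulated-minus-experimental differences.
#' @param tol Coefficient magnitude below which a term counts as zero.
#' @return A list of class `islet_quadfit`: `roots` (numeric, possibly
#'   empty), `coef` (c, b, a), `degenerate`, and the input points.
#' @export
#' @examples
#' quadratic_intercepts(1:5, (1:5 - 1) * (1:5 - 3))
quadratic_intercepts <- function(rlp_d, difference, tol = 1e-10) {
  stopifnot(length(rlp_d) == length(difference), length(rlp_d) >= 3)
  o <- order(rlp_d)
  x <- rlp_d[o]
  y <- difference[o]
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  a <- cf[[3]]
  b <- cf[[2]]
  cc <- cf[[1]]
  scale <- max(abs(y), 1)
  degenerate <- abs(a) < tol * scale && abs(b) < tol * scale
  roots <- if (degenerate) {
    numeric(0)
  } else if (abs(a) < tol * scale) {
    -cc / b
  } else {
    z <- polyroot(c(cc, b, a))
    Re(z[abs(Im(z)) < 1e-8])
  }
  roots <- sort(roots[roots >= min(x) - 1e-9 & roots <= max(x) + 1e-9])
  structure(
    list(roots = roots, coef = c(c = cc, b = b, a = a),
         degenerate = degenerate,
         points = tibble::tibble(rlp_d = x, difference = y)),
    class = "islet_quadfit"
  )
}

#' @export
print.islet_quadfit <- function(x, ...) {
  cat("<islet_quadfit>",
      if (length(x$roots) == 0) "no in-range roots"
      else paste("roots:", paste(signif(x$roots, 6), collapse = ", ")),
      if (x$degenerate) "(degenerate fit)" else "", "\n")
  invisible(x)
}

#' Summarise measure-equilibria of a model family
#'
#' Applies [quadratic_intercepts()] to every (measure, rlp_a) difference
#' curve and reports, per measure, the range of in-sweep roots over `rlp_a`,
#' plus the grand mean over all roots of all measures. A family whose curves
#' never produce an in-range root is flagged as having no equilibrium.
#'
#' @param curves Output of [difference_curves()] for one family.
#' @return A list of class `equilibrium_summary` with `by_measure` (tibble:
#'   `measure`, `n_roots`, `root_min`, `root_max`), `roots` (tibble of all
#'   roots), `grand_mean`, and `no_equilibrium`.
#' @export
summarize_equilibria <- function(curves) {
  curves <- tibble::as_tibble(curves)
  fits <- curves |>
    dplyr::group_by(.data$measure, .data$rlp_a) |>
    dplyr::summarise(
      fit = list(quadratic_intercepts(.data$rlp_d, .data$difference)),
      .groups = "drop"
    )
  roots <- fits |>
    dplyr::mutate(root = purrr::map(.data$fit, "roots")) |>
    dplyr::select(-"fit") |>
    tidyr::unnest("root")
  root_ranges <- if (nrow(roots) > 0) {
    roots |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(n_roots = dplyr::n(), root_min = min(.data$root),
                       root_max = max(.data$root), .groups = "drop")
  } else {
    tibble::tibble(measure = character(), n_roots = integer(),
                   root_min = double(), root_max = double())
  }
  by_measure <- fits |>
    dplyr::distinct(.data$measure) |>
    dplyr::left_join(root_ranges, by = "measure") |>
    dplyr::mutate(n_roots = dplyr::coalesce(.data$n_roots, 0L))
  structure(
    list(by_measure = by_measure, roots = roots,
         grand_mean = if (nrow(roots) > 0) mean(roots$root) else NA_real_,
         no_equilibrium = nrow(roots) == 0),
    class = "equilibrium_summary"
  )
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  if (x$no_equilibrium) {
    cat("<equilibrium_summary> no equilibrium solutions found\n")
  } else {
    cat(sprintf("<equilibrium_summary> %d roots, grand mean %.3f\n",
                nrow(x$roots), x$grand_mean))
    print(x$by_measure)
  }
  invisible(x)
}
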