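#' Tidy an islet graph into its edge list
#'
#' @param x An `islet_graph`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `distance`.
#' @exportS3Method generics::tidy
tidy.islet_graph <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row summary of an islet graph
#'
#' @param x An `islet_graph`.
#' @param ... Unused.
#' @return The [islet_measures()] row plus the neighborhood radius.
#' @exportS3Method generics::glance
glance.islet_graph <- function(x, ...) {
  dplyr::mutate(islet_measures(x), radius = x$params$radius)
}

#' Tidy a quadratic-intercept fit into its roots
#'
#' @param x An `islet_quadfit`.
#' @param ... Unused.
#' @return A tibble with one row per in-range root.
#' @exportS3Method generics::tidy
tidy.islet_quadfit <- function(x, ...) {
  tibble::tibble(root = x$roots)
}

#' One-row summary of a quadratic-intercept fit
#'
#' @param x An `islet_quadfit`.
#' @param ... Unused.
#' @return A tibble with the fitted coefficients, root count and the
#'   degeneracy flag.
#' @exportS3Method generics::glance
glance.islet_quadfit <- function(x, ...) {
  tibble::tibble(c = x$coef[["c"]], b = x$coef[["b"]], a = x$coef[["a"]],
                 n_roots = length(x$roots), degenerate = x$degenerate)
}

#' Tidy a simulation result
#'
#' @param x An `islet_sim` tibble from [run_simulation()].
#' @param ... Unused.
#' @return The underlying tibble without the simulation attributes.
#' @exportS3Method generics::tidy
tidy.islet_sim <- function(x, ...) {
  out <- x
  attr(out, "model") <- NULL
  attr(out, "config") <- NULL
  attr(out, "n_skipped_islets") <- NULL
  class(out) <- setdiff(class(out), "islet_sim")
  tibble::as_tibble(out)
}

#' One-row summary of a simulation result
#'
#' Aggregates the final recorded iteration over islets and replicates.
#'
#' @param x An `islet_sim` tibble.
#' @param ... Unused.
#' @return A tibble with the model code, replicate count, islet count and
#'   the cell-weighted mean degree, mean components per islet and cells per
#'   component at the final iteration.
#' @exportS3Method generics::glance
glance.islet_sim <- function(x, ...) {
  model <- attr(x, "model")
  fin <- dplyr::filter(tibble::as_tibble(x),
                       .data$iteration == max(.data$iteration))
  tibble::tibble(
    code = model$code, basis = model$basis,
    n_islets = dplyr::n_distinct(paste(fin$subject_id, fin$islet_id)),
    n_replicates = max(fin$replicate),
    mean_degree = sum(fin$mean_degree * fin$n_vertices) /
      sum(fin$n_vertices),
    n_components = mean(fin$n_components),
    cells_per_component = sum(fin$n_vertices) / sum(fin$n_components)
  )
}
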