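# Independent brute-force oracles, deliberately written as plain, slow R so
# they share no code with the package implementation.

# Angular separation between directions focal->a and focal->b.
oracle_angle <- function(cells, focal, a, b) {
  va <- c(cells$x[a] - cells$x[focal], cells$y[a] - cells$y[focal])
  vb <- c(cells$x[b] - cells$x[focal], cells$y[b] - cells$y[focal])
  if ("z" %in% names(cells)) {
    va <- c(va, cells$z[a] - cells$z[focal])
    vb <- c(vb, cells$z[b] - cells$z[focal])
  }
  cosang <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  acos(pmin(1, pmax(-1, cosang)))
}

# Naive re-implementation of the shadow predicate: sorted traversal, accepted
# neighbours cast shadows of half-angle atan(cell_radius / d), candidates
# rejected on strict inequality.
oracle_neighbors <- function(cells, focal_row, radius, cell_radius = 4) {
  n <- nrow(cells)
  d <- sqrt((cells$x - cells$x[focal_row])^2 +
              (cells$y - cells$y[focal_row])^2 +
              (if ("z" %in% names(cells)) (cells$z - cells$z[focal_row])^2 else 0))
  cand <- setdiff(which(d <= radius & seq_len(n) != focal_row), integer(0))
  cand <- cand[order(d[cand], cells$cell_id[cand])]
  acc <- integer(0)
  for (cc in cand) {
    shadowed <- FALSE
    for (p in acc) {
      if (oracle_angle(cells, focal_row, cc, p) < atan(cell_radius / d[p])) {
        shadowed <- TRUE
        break
      }
    }
    if (!shadowed) acc <- c(acc, cc)
  }
  acc
}

oracle_edges <- function(cells, radius, cell_radius = 4,
                         symmetrize = "mutual") {
  n <- nrow(cells)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, oracle_neighbors(cells, i, radius, cell_radius)] <- TRUE
  keep <- if (symmetrize == "mutual") adj & t(adj) else adj | t(adj)
  which(keep & upper.tri(keep), arr.ind = TRUE)
}

# Components as equivalence classes of reachability, by boolean transitive
# closure (matrix powering), independent of any graph library.
oracle_component_sizes <- function(n, edges) {
  reach <- diag(n) > 0
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      reach[edges[k, 1], edges[k, 2]] <- TRUE
      reach[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  classes <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  sort(vapply(strsplit(classes, ","), length, integer(1)))
}

# Random hard-core-free point scatter for oracle comparisons (distinct
# positions, no structure assumed).
random_cells <- function(n, span = 40, three_d = FALSE) {
  tib <- tibble::tibble(
    cell_id = seq_len(n),
    x = stats::runif(n, 0, span),
    y = stats::runif(n, 0, span)
  )
  if (three_d) tib$z <- stats::runif(n, 0, span)
  tib
}

# Polar construction helper for hand-built geometries.
polar_cells <- function(dist, angle_deg, ids = seq_along(dist) + 1L) {
  tibble::tibble(
    cell_id = c(1L, ids),
    x = c(0, dist * cos(angle_deg * pi / 180)),
    y = c(0, dist * sin(angle_deg * pi / 180))
  )
}
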