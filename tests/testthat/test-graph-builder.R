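test_that("shadow_angle follows the occlusion geometry", {
  expect_equal(shadow_angle(4), pi / 4)
  expect_equal(shadow_angle(8), atan(0.5), tolerance = 1e-12)
  d <- seq(1, 100, by = 0.5)
  expect_true(all(diff(shadow_angle(d)) < 0))      # strictly decreasing
  expect_lt(shadow_angle(1e9), 1e-8)               # vanishes at distance
  expect_true(all(shadow_angle(d) > 0 & shadow_angle(d) < pi / 2))
  expect_error(shadow_angle(0), class = "isletgraph_domain_error")
})

test_that("directed neighbours handle the collinear occlusion case", {
  cells <- tibble::tibble(cell_id = 1:3, x = c(0, 8, 16), y = 0)
  # far cell beyond radius 10
  expect_equal(directed_neighbors(cells, 1, neighborhood_params(radius = 10)),
               2L)
  # radius 16: far cell in range but exactly behind the near one
  expect_equal(directed_neighbors(cells, 1, neighborhood_params(radius = 16)),
               2L)
  # single candidate within radius is always accepted
  two <- tibble::tibble(cell_id = 1:2, x = c(0, 9), y = 0)
  expect_equal(directed_neighbors(two, 1, neighborhood_params(radius = 10)),
               2L)
})

test_that("a nine-cell occlusion configuration reproduces its accepted set", {
  # focal cell 1 at the origin; cells 3 and 5 sit in the shadows of cells 2
  # and 4, cell 8 is beyond the radius
  cells <- polar_cells(
    dist = c(5, 9.2, 6, 9.5, 7, 8, 12, 9),
    angle_deg = c(0, 10, 90, 105, 180, 250, 300, 320),
    ids = 2:9
  )
  got <- directed_neighbors(cells, 1, neighborhood_params(radius = 10))
  expect_setequal(got, c(2L, 4L, 6L, 7L, 9L))
  # and the independent oracle agrees
  expect_setequal(cells$cell_id[oracle_neighbors(cells, 1, 10)], got)
})

test_that("build_graph matches the brute-force oracle on random scatters", {
  set.seed(20260921)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    cells <- random_cells(n, span = 30)
    radius <- runif(1, 6, 16)
    sym <- sample(c("mutual", "union"), 1)
    p <- neighborhood_params(radius = radius, symmetrize = sym)
    g <- build_islet_graph(cells, p)
    got <- g$edges[c("from", "to")]
    exp_idx <- oracle_edges(cells, radius, symmetrize = sym)
    exp_edges <- tibble::tibble(
      from = pmin(cells$cell_id[exp_idx[, 1]], cells$cell_id[exp_idx[, 2]]),
      to = pmax(cells$cell_id[exp_idx[, 1]], cells$cell_id[exp_idx[, 2]])
    )
    expect_equal(dplyr::arrange(got, from, to),
                 dplyr::arrange(exp_edges, from, to),
                 ignore_attr = TRUE)
    # every edge respects the distance threshold
    expect_true(all(g$edges$distance <= radius + 1e-12))
  }
})

test_that("3d graphs match the oracle with cone-angle shadowing", {
  set.seed(99)
  for (rep in 1:40) {
    cells <- random_cells(sample(3:10, 1), span = 25, three_d = TRUE)
    p <- neighborhood_params(radius = 12)
    g <- build_islet_graph(cells, p)
    exp_idx <- oracle_edges(cells, 12)
    expect_equal(nrow(g$edges), nrow(exp_idx))
    if (nrow(exp_idx) > 0) {
      exp_edges <- tibble::tibble(
        from = pmin(cells$cell_id[exp_idx[, 1]], cells$cell_id[exp_idx[, 2]]),
        to = pmax(cells$cell_id[exp_idx[, 1]], cells$cell_id[exp_idx[, 2]]))
      expect_equal(dplyr::arrange(g$edges[c("from", "to")], from, to),
                   dplyr::arrange(exp_edges, from, to), ignore_attr = TRUE)
    }
  }
})

test_that("degenerate and deterministic cases behave as specified", {
  single <- tibble::tibble(cell_id = 1L, x = 0, y = 0)
  g1 <- build_islet_graph(single)
  expect_equal(nrow(g1$vertices), 1)
  expect_equal(nrow(g1$edges), 0)

  # equilateral triangle, side 9: 60 degree separations beat atan(4/9)
  tri <- tibble::tibble(cell_id = 1:3, x = c(0, 9, 4.5),
                        y = c(0, 0, 9 * sqrt(3) / 2))
  expect_equal(nrow(build_islet_graph(tri, neighborhood_params(10))$edges), 3)

  # identical input -> identical graph
  set.seed(5)
  cells <- random_cells(10)
  ga <- build_islet_graph(cells)
  gb <- build_islet_graph(cells)
  expect_identical(ga$edges, gb$edges)

  # coincident points are a geometry error
  bad <- tibble::tibble(cell_id = 1:2, x = c(1, 1), y = c(2, 2))
  expect_error(build_islet_graph(bad), "coincident")
})

test_that("without shadowing the graph is exactly the distance threshold", {
  # well-separated angular spread: no candidate occluded, so the edge set
  # equals all pairs within the radius
  set.seed(11)
  cells <- polar_cells(dist = c(9, 9.5, 8.7, 9.9),
                       angle_deg = c(0, 95, 190, 275), ids = 2:5)
  g <- build_islet_graph(cells, neighborhood_params(radius = 10))
  d <- as.matrix(stats::dist(cells[c("x", "y")]))
  expect_equal(nrow(g$edges), sum(d[upper.tri(d)] <= 10))
})

test_that("edge removal fraction counts occluded candidates", {
  two <- tibble::tibble(cell_id = 1:2, x = c(0, 9), y = 0)
  expect_equal(edge_removal_fraction(two, neighborhood_params(10)), 0)

  triple <- tibble::tibble(cell_id = 1:3, x = c(0, 8, 16), y = 0)
  expect_equal(edge_removal_fraction(triple, neighborhood_params(17)), 1 / 3)

  # no pair within the radius: undefined
  far <- tibble::tibble(cell_id = 1:2, x = c(0, 99), y = 0)
  expect_true(is.na(edge_removal_fraction(far, neighborhood_params(10))))

  # stochastic trend: removal grows with the radius on average
  set.seed(3)
  frac_at <- function(radius) {
    mean(vapply(1:40, function(i) {
      cells <- random_cells(12, span = 30)
      f <- edge_removal_fraction(cells, neighborhood_params(radius))
      if (is.na(f)) 0 else f
    }, numeric(1)))
  }
  expect_gt(frac_at(16), frac_at(8))
})
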