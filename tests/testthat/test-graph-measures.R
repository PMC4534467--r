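path4 <- function() {
  # collinear chain spaced 9 um: consecutive cells linked at radius 10
  tibble::tibble(cell_id = 1:4, x = c(0, 9, 18, 27), y = 0)
}

test_that("degrees match hand counts", {
  g <- build_islet_graph(path4(), neighborhood_params(10))
  expect_equal(degree_of(g, 1), 1)
  expect_equal(degree_of(g, 2), 2)
  expect_error(degree_of(g, 99), class = "isletgraph_lookup_error")

  tri <- tibble::tibble(cell_id = 1:3, x = c(0, 9, 4.5),
                        y = c(0, 0, 9 * sqrt(3) / 2))
  expect_equal(vertex_degrees(build_islet_graph(tri))$degree, rep(2L, 3))

  lone <- build_islet_graph(tibble::tibble(cell_id = 1L, x = 0, y = 0))
  expect_equal(vertex_degrees(lone)$degree, 0L)
})

test_that("islet measures satisfy their accounting invariants", {
  # 5 isolated vertices
  iso <- tibble::tibble(cell_id = 1:5, x = seq(0, 200, by = 50), y = 0)
  m <- islet_measures(build_islet_graph(iso, neighborhood_params(10)))
  expect_equal(m$n_components, 5)
  expect_equal(m$n_singular, 5)
  expect_equal(m$mean_degree, 0)
  expect_equal(m$cells_per_component, 1)
  expect_true(is.na(m$cells_per_nonsingular))

  # path of four: one nonsingular component
  mp <- islet_measures(build_islet_graph(path4(), neighborhood_params(10)))
  expect_equal(mp$mean_degree, 1.5)
  expect_equal(mp$n_nonsingular, 1)
  expect_equal(mp$cells_per_nonsingular, 4)
})

test_that("components match the transitive-closure oracle on random graphs", {
  set.seed(2468)
  for (rep in 1:60) {
    cells <- random_cells(sample(2:15, 1), span = 35)
    g <- build_islet_graph(cells, neighborhood_params(10))
    m <- islet_measures(g)
    em <- cbind(match(g$edges$from, cells$cell_id),
                match(g$edges$to, cells$cell_id))
    sizes <- oracle_component_sizes(nrow(cells), em)
    expect_equal(m$n_components, length(sizes))
    expect_equal(m$n_singular, sum(sizes == 1))
    expect_equal(m$n_vertices, sum(sizes))
    # mean degree identity 2E/V
    expect_equal(m$mean_degree, 2 * m$n_edges / m$n_vertices)
  }
})

test_that("bridging two components reduces the count by exactly one", {
  cells <- tibble::tibble(cell_id = 1:4, x = c(0, 9, 40, 49), y = 0)
  g <- build_islet_graph(cells, neighborhood_params(10))
  before <- islet_measures(g)
  expect_equal(before$n_components, 2)
  g$edges <- dplyr::bind_rows(g$edges,
                              tibble::tibble(from = 2L, to = 3L,
                                             distance = 31))
  after <- islet_measures(g)
  expect_equal(after$n_components, before$n_components - 1)
})

test_that("effective diameter uses the padded equivalent-circle rule", {
  # dense disc of radius 25 -> effective diameter near 2 * (25 + 4)
  set.seed(10)
  th <- runif(2000, 0, 2 * pi)
  rr <- 25 * sqrt(runif(2000))
  disc <- tibble::tibble(x = rr * cos(th), y = rr * sin(th))
  expect_equal(effective_diameter(disc), 2 * 29, tolerance = 0.02)

  expect_equal(classify_islet_size(disc), "small")  # 58 < 60
  wide <- tibble::tibble(x = c(0, 200, 100), y = c(0, 0, 150))
  expect_equal(classify_islet_size(wide), "large")
  single <- tibble::tibble(x = 0, y = 0)
  expect_equal(effective_diameter(single), 8)
  expect_equal(classify_islet_size(single), "small")
  collinear <- tibble::tibble(x = c(0, 30, 60), y = 0)
  expect_equal(effective_diameter(collinear), 68)
})

test_that("aggregation weights degrees by cell and components by islet", {
  lone <- islet_measures(build_islet_graph(
    tibble::tibble(cell_id = 1L, x = 0, y = 0)))
  tri <- islet_measures(build_islet_graph(
    tibble::tibble(cell_id = 1:3, x = c(0, 9, 4.5),
                   y = c(0, 0, 9 * sqrt(3) / 2))))
  agg <- aggregate_measures(dplyr::bind_rows(lone, tri))
  expect_equal(agg$mean_degree, (0 + 2 + 2 + 2) / 4)
  expect_equal(agg$n_components, 1)  # each islet has one component

  one_comp <- islet_measures(build_islet_graph(path4()))
  three_comp <- islet_measures(build_islet_graph(
    tibble::tibble(cell_id = 1:3, x = c(0, 50, 100), y = 0)))
  expect_equal(aggregate_measures(
    dplyr::bind_rows(one_comp, three_comp))$n_components, 2)

  # two identical graphs aggregate to the single-graph values
  twice <- aggregate_measures(dplyr::bind_rows(tri, tri))
  expect_equal(twice$mean_degree, tri$mean_degree)
  expect_equal(twice$cells_per_component, tri$cells_per_component)

  expect_error(aggregate_measures(tibble::tibble()),
               class = "isletgraph_value_error")
})

test_that("group comparison applies Mann-Whitney with Bonferroni gates", {
  sep <- compare_groups(c(1, 2, 3), c(11, 12, 13), n_tests = 1)
  expect_equal(sep$p_value, 0.1)  # exact two-sided, U = 0

  expect_warning(tied <- compare_groups(rep(2, 5), rep(2, 4), n_tests = 1),
                 "tied")
  expect_equal(tied$p_value, 1)
  expect_false(tied$significant)

  ident <- suppressWarnings(compare_groups(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$p_value, 1, tolerance = 1e-6)

  # p = 0.01 is not significant against the 64-test Bonferroni threshold
  gate <- compare_groups(c(1, 2, 3), c(11, 12, 13), n_tests = 64)
  expect_equal(gate$threshold, 0.05 / 64)
  set.seed(1)
  big <- compare_groups(rnorm(300), rnorm(300, 0.4), n_tests = 64)
  expect_true(big$p_value < 0.05 && (big$significant ==
                                       (big$p_value < 0.05 / 64)))
})
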