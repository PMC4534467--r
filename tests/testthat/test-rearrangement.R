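test_that("relative-likelihood kernels satisfy their identities", {
  x <- seq(-3, 12, by = 0.25)
  for (rlp in 0:7) {
    expect_equal(rl_value(x, "P", rlp) + rl_value(x, "M", rlp),
                 rep(1, length(x)), tolerance = 1e-12)
    expect_equal(rl_value(rlp, "P", rlp), 0.5)
    expect_equal(rl_value(rlp, "M", rlp), 0.5)
    expect_true(all(diff(rl_value(x, "P", rlp)) > 0))   # increasing
    expect_true(all(diff(rl_value(x, "M", rlp)) < 0))   # decreasing
  }
  expect_equal(rl_value(4, "P", 2), 0.5 + 0.5 * tanh(2), tolerance = 1e-12)
})

test_that("model codes round-trip through the shorthand", {
  m <- model_spec("MP01", basis = "component")
  expect_equal(m$add_dir, "M")
  expect_equal(m$del_dir, "P")
  expect_equal(m$rlp_a, 0)
  expect_equal(m$rlp_d, 1)
  expect_equal(m$code, "MP01")
  m2 <- model_spec(add_dir = "P", del_dir = "P", rlp_a = 4, rlp_d = 2)
  expect_equal(m2$code, "PP42")
})

test_that("vertex selection follows the normalised relative likelihoods", {
  # path of three: degrees 1, 2, 1; P kernel at rlp = 2 weights the middle
  # vertex 0.5 and the ends 0.5 - 0.5 tanh(1)
  cells <- tibble::tibble(cell_id = 1:3, x = c(0, 9, 18), y = 0)
  g <- build_islet_graph(cells, neighborhood_params(10))
  w_end <- rl_value(1, "P", 2)
  w_mid <- rl_value(2, "P", 2)
  p_mid <- w_mid / (2 * w_end + w_mid)
  set.seed(123)
  draws <- vapply(1:4000, function(i) select_vertex(g, "P", 2, "degree"),
                  integer(1))
  phat <- mean(draws == 2)
  expect_lt(abs(phat - p_mid), 3 * sqrt(p_mid * (1 - p_mid) / 4000))

  # all vertices equivalent -> near-uniform selection
  set.seed(5)
  tri <- build_islet_graph(tibble::tibble(cell_id = 1:3, x = c(0, 9, 4.5),
                                          y = c(0, 0, 9 * sqrt(3) / 2)))
  u <- table(vapply(1:3000, function(i) select_vertex(tri, "M", 9, "degree"),
                    integer(1)))
  expect_true(all(abs(u / 3000 - 1 / 3) < 0.04))

  # component basis weights by cluster size
  pair_lone <- build_islet_graph(
    tibble::tibble(cell_id = 1:3, x = c(0, 9, 60), y = 0))
  set.seed(6)
  dc <- vapply(1:4000, function(i) select_vertex(pair_lone, "P", 9, "component"),
               integer(1))
  w <- rl_value(c(2, 2, 1), "P", 9)
  expect_lt(abs(mean(dc == 3) - w[3] / sum(w)), 0.03)
})

test_that("steric addition preserves spacing and placement geometry", {
  set.seed(77)
  spec <- cohort_spec()
  cells <- generate_islet(30, spec, size = "large")
  g <- build_islet_graph(dplyr::select(cells, cell_id, x, y))
  # the islet's observed minimum spacing, capped at the placement minimum
  d_min <- min(stats::dist(cells[c("x", "y")]), 8)

  for (i in 1:100) {
    parent <- sample(g$vertices$cell_id, 1)
    px <- g$vertices$x[match(parent, g$vertices$cell_id)]
    py <- g$vertices$y[match(parent, g$vertices$cell_id)]
    g2 <- add_vertex(g, parent, d_min = d_min)
    expect_equal(nrow(g2$vertices), nrow(g$vertices) + 1)
    # exhaustive pairwise audit
    expect_gte(min(stats::dist(g2$vertices[c("x", "y")])), d_min - 1e-9)
    # the newcomer sits in the placement annulus and the parent never moves
    vnew <- dplyr::anti_join(g2$vertices, g$vertices, by = "cell_id")
    expect_equal(nrow(vnew), 1)
    dpar <- sqrt((vnew$x - px)^2 + (vnew$y - py)^2)
    expect_true(dpar >= 8 - 1e-9 && dpar <= 13 + 1e-9)
    pmoved <- g2$vertices[match(parent, g2$vertices$cell_id), c("x", "y")]
    expect_equal(c(pmoved$x, pmoved$y), c(px, py))
  }
})

test_that("an isolated parent gains a neighbour without disturbing others", {
  cells <- tibble::tibble(cell_id = 1:2, x = c(0, 50), y = 0)
  g <- build_islet_graph(cells)
  set.seed(8)
  g2 <- add_vertex(g, 1, d_min = 8)
  expect_equal(nrow(g2$vertices), 3)
  expect_equal(g2$vertices$x[g2$vertices$cell_id == 2], 50)  # far cell fixed
  vnew <- g2$vertices[g2$vertices$cell_id == 3, ]
  expect_true(sqrt(vnew$x^2 + vnew$y^2) <= 13 + 1e-9)
})

test_that("the simulation conserves cells, spacing and its RNG contract", {
  set.seed(41)
  tbl <- generate_cohort(cohort_spec(n_islets = 12))
  beta <- filter_cells(tbl, "beta")
  model <- model_spec("PM21", basis = "degree")
  cfg <- sim_config(n_iterations = 25, n_replicates = 2, trajectory = TRUE)

  set.seed(2026)
  s1 <- suppressMessages(run_simulation(beta, model, cfg))
  set.seed(2026)
  s2 <- suppressMessages(run_simulation(beta, model, cfg))
  expect_identical(tidy(s1), tidy(s2))

  counts <- dplyr::count(beta, subject_id, islet_id)
  chk <- dplyr::left_join(tidy(s1), counts, by = c("subject_id", "islet_id"))
  expect_true(all(chk$n_vertices == chk$n))           # every iteration
  expect_true(all(chk$min_pairdist >= chk$d_min - 1e-9))
})

test_that("component-dependent deletion pressure fragments clusters", {
  # MP with a high deletion midpoint removes cells from large clusters and
  # reattaches them loosely: more, smaller components than at rlp_d = 1
  set.seed(61)
  spec <- cohort_spec()
  islet <- generate_islet(45, spec, size = "large")
  beta_like <- dplyr::mutate(islet, cell_type = "beta")
  cfg <- sim_config(n_iterations = 100, n_replicates = 6)
  run_at <- function(rlp_d) {
    m <- model_spec(add_dir = "M", del_dir = "P", rlp_a = 3, rlp_d = rlp_d,
                    basis = "component")
    set.seed(100 + rlp_d)
    glance(suppressMessages(run_simulation(beta_like, m, cfg)))
  }
  lo <- run_at(1)
  hi <- run_at(5)
  expect_gt(hi$n_components, lo$n_components)
  expect_lt(hi$cells_per_component, lo$cells_per_component)
})

test_that("convergence diagnostics flatten as replicates accumulate", {
  grid <- tidyr::expand_grid(rlp_a = 1:2, rlp_d = 1:2, replicate = 1:40)
  ident <- dplyr::mutate(grid, mean_degree = 1.5, n_components = 4,
                         cells_per_component = 2)
  d0 <- convergence_diagnostics(ident)
  late <- dplyr::filter(d0, i >= 2)
  expect_true(all(late$max_sd == 0))
  expect_true(all(late$max_dmean == 0))

  set.seed(17)
  noisy <- dplyr::mutate(grid,
                         mean_degree = rnorm(dplyr::n()),
                         n_components = rnorm(dplyr::n(), 4),
                         cells_per_component = rnorm(dplyr::n(), 2))
  dn <- convergence_diagnostics(noisy)
  dd <- dplyr::filter(dn, measure == "mean_degree", i >= 2)
  # law of large numbers: the change in mean decays like 1/i
  slope <- coef(lm(log(dd$max_dmean) ~ log(dd$i)))[2]
  expect_lt(slope, -0.5)
  # the maximum over parameter pairs dominates any single pair
  one_pair <- dplyr::filter(noisy, rlp_a == 1, rlp_d == 1)
  m20 <- abs(mean(one_pair$mean_degree[1:20]) -
               mean(one_pair$mean_degree[1:19]))
  expect_gte(dn$max_dmean[dn$i == 20 & dn$measure == "mean_degree"], m20)
})
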