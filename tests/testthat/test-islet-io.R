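make_file <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a small file ingests to the expected islet table", {
  path <- make_file(c(
    "subject_id,islet_id,cell_id,x,y,cell_type",
    "C1,1,1,0,0,beta",
    "C1,2,1,10,0,beta",
    "C1,3,1,20,0,beta"
  ))
  tbl <- read_islet_table(path, group = "control")
  expect_equal(nrow(tbl), 3)
  expect_equal(dplyr::n_distinct(tbl$islet_id), 3)
  expect_equal(unique(tbl$group), "control")
  expect_equal(unique(tbl$cell_type), "beta")
})

test_that("dialects map foreign headers, column orders and type tokens", {
  path <- make_file(c(
    "isl\tcell\tsubj\txpos\typos\ttyp",
    "1\t1\tC1\t0.5\t1.5\tB",
    "1\t2\tC1\t9.5\t1.5\ta"
  ), ext = ".tsv")
  tbl <- read_islet_table(path, group = "t2d",
                          dialect = islet_dialect(subject = "subj",
                                                  islet = "isl",
                                                  cell = "cell", x = "xpos",
                                                  y = "ypos",
                                                  cell_type = "typ"))
  expect_equal(tbl$cell_type, c("beta", "alpha"))
  expect_equal(tbl$x, c(0.5, 9.5))
  expect_equal(unique(tbl$group), "t2d")
})

test_that("malformed files fail with the specific schema/parse/value errors", {
  missing_col <- make_file(c("subject_id,islet_id,cell_id,x,cell_type",
                             "C1,1,1,0,beta"))
  expect_error(read_islet_table(missing_col), class = "isletgraph_schema_error")

  bad_coord <- make_file(c("subject_id,islet_id,cell_id,x,y,cell_type",
                           "C1,1,1,0,zero,beta"))
  expect_error(read_islet_table(bad_coord), class = "isletgraph_parse_error",
               regexp = "row")

  bad_type <- make_file(c("subject_id,islet_id,cell_id,x,y,cell_type",
                          "C1,1,1,0,0,gamma"))
  expect_error(read_islet_table(bad_type), class = "isletgraph_value_error",
               regexp = "gamma")

  dup <- make_file(c("subject_id,islet_id,cell_id,x,y,cell_type",
                     "C1,1,1,0,0,beta",
                     "C1,1,1,5,5,beta"))
  expect_error(read_islet_table(dup), class = "isletgraph_uniqueness_error",
               regexp = "C1, 1, 1")
})

test_that("read -> write -> read round-trips field for field", {
  set.seed(42)
  tbl <- generate_cohort(cohort_spec(n_islets = 8), subject_id = "C9")
  path <- withr::local_tempfile(fileext = ".csv")
  write_islet_table(tbl, path)
  back <- read_islet_table(path, group = "control")
  expect_equal(back, tbl)
})

test_that("filter_cells keeps one type and reports emptied islets", {
  tbl <- tibble::tibble(
    subject_id = "C1", group = "control",
    islet_id = c(1L, 1L, 1L, 1L, 1L, 2L),
    cell_id = 1:6,
    x = c(0, 10, 20, 30, 40, 0), y = 0,
    cell_type = c("alpha", "alpha", "beta", "beta", "beta", "delta")
  )
  beta <- filter_cells(tbl, "beta")
  expect_equal(nrow(beta), 3)
  expect_equal(unique(beta$islet_id), 1L)
  expect_equal(attr(beta, "n_dropped_islets"), 1L)

  none <- filter_cells(dplyr::filter(tbl, cell_type == "alpha"), "delta")
  expect_equal(nrow(none), 0)
})

test_that("cohort summaries are additive across subjects and size classes", {
  simple <- tibble::tibble(
    subject_id = "C1", group = "control",
    islet_id = rep(1:2, each = 5), cell_id = rep(1:5, 2),
    x = rep(seq(0, 36, by = 9), 2), y = 0, cell_type = "beta"
  )
  s <- summarize_islets(simple, split_size = FALSE)
  expect_equal(s$n_islets[s$subject_id == "C1"], 2)
  expect_equal(s$n_cells[s$subject_id == "C1"], 10)

  set.seed(7)
  two <- dplyr::bind_rows(
    generate_cohort(cohort_spec(n_islets = 10), subject_id = "C1"),
    generate_cohort(cohort_spec(n_islets = 15), subject_id = "C2")
  )
  s2 <- summarize_islets(two)
  per_subject <- dplyr::filter(s2, subject_id != "TOTAL")
  total <- dplyr::filter(s2, subject_id == "TOTAL")
  expect_equal(sum(per_subject$n_islets), total$n_islets)
  expect_equal(sum(per_subject$n_cells), total$n_cells)
  expect_equal(per_subject$n_cells_large + per_subject$n_cells_small,
               per_subject$n_cells)
  expect_equal(per_subject$n_islets_large + per_subject$n_islets_small,
               per_subject$n_islets)
})
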