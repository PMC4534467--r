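#' Column dialect for cell-coordinate files
#'
#' Deposited coordinate files name their columns in whatever way the imaging
#' pipeline chose; a dialect maps the actual header (or column order) onto the
#' canonical schema: subject id, islet id, cell id, x, y, optional z, and cell
#' type. Cell-type tokens are normalised through `type_map`, which by default
#' accepts common spellings ("beta", "b", "B", Greek letters, ...).
#'
#' @param subject,islet,cell,x,y,z,cell_type Column names (or 1-based column
#'   indices when `header = FALSE`) in the file. `z` may be `NULL` for 2d data.
#' @param delim Field delimiter; `NULL` autodetects comma vs tab.
#' @param header Does the file carry a header row?
#' @param type_map Named character vector mapping raw cell-type tokens
#'   (lower-cased) to `"alpha"`, `"beta"` or `"delta"`.
#' @return A list of class `islet_dialect`.
#' @export
#' @examples
#' islet_dialect(subject = "subj", x = "xpos", y = "ypos")
islet_dialect <- function(subject = "subject_id", islet = "islet_id",
                          cell = "cell_id", x = "x", y = "y", z = NULL,
                          cell_type = "cell_type",
                          delim = NULL, header = TRUE,
                          type_map = default_type_map()) {
  structure(
    list(subject = subject, islet = islet, cell = cell,
         x = x, y = y, z = z, cell_type = cell_type,
         delim = delim, header = header, type_map = type_map),
    class = "islet_dialect"
  )
}

default_type_map <- function() {
  c("alpha" = "alpha", "a" = "alpha", "α" = "alpha", "1" = "alpha",
    "beta" = "beta", "b" = "beta", "β" = "beta", "2" = "beta",
    "delta" = "delta", "d" = "delta", "δ" = "delta", "3" = "delta")
}

#' Read a cell-coordinate dataset into a validated islet table
#'
#' Reads one delimited text file of per-cell records (one row per cell) and
#' returns the canonical islet table: a tibble with columns `subject_id`,
#' `group`, `islet_id`, `cell_id`, `x`, `y`, optionally `z`, and `cell_type`.
#' The group label (control vs t2d) is a property of the file, not inferred
#' from subject labels, and is attached to every record.
#'
#' @param path Path to a delimited text file.
#' @param group `"control"` or `"t2d"`; attached to every record read.
#' @param dialect An [islet_dialect()] describing the file layout.
#' @return A validated islet table (tibble). Coordinates are micrometres.
#' @export
read_islet_table <- function(path, group = c("control", "t2d"),
                             dialect = islet_dialect()) {
  group <- match.arg(group)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "isletgraph_io_error")
  }
  delim <- dialect$delim %||% guess_delim(path)
  raw <- readr::read_delim(
    path, delim = delim,
    col_names = isTRUE(dialect$header),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  resolve <- function(key) {
    spec <- dialect[[key]]
    if (is.null(spec)) return(NULL)
    if (is.numeric(spec)) {
      if (spec > ncol(raw)) {
        abort(paste0("dialect maps '", key, "' to column ", spec,
                     " but the file has only ", ncol(raw), " columns"),
              class = "isletgraph_schema_error")
      }
      return(names(raw)[spec])
    }
    if (!spec %in% names(raw)) {
      abort(paste0("missing column '", spec, "' (schema field '", key, "'); ",
                   "columns present: ", paste(names(raw), collapse = ", ")),
            class = "isletgraph_schema_error")
    }
    spec
  }
  cols <- purrr::map(
    setNames(c("subject", "islet", "cell", "x", "y", "cell_type"),
             c("subject", "islet", "cell", "x", "y", "cell_type")),
    resolve
  )
  zcol <- if (!is.null(dialect$z) &&
              (is.numeric(dialect$z) || dialect$z %in% names(raw))) {
    resolve("z")
  }

  parse_num <- function(x, field) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort(paste0("non-numeric ", field, " at data row(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   ": ", paste(head(x[bad], 5), collapse = ", ")),
            class = "isletgraph_parse_error")
    }
    out
  }

  type_raw <- tolower(trimws(raw[[cols$cell_type]]))
  known <- type_raw %in% names(dialect$type_map)
  if (any(!known)) {
    bad <- which(!known)
    abort(paste0("unknown cell_type token(s) at data row(s) ",
                 paste(head(bad, 5), collapse = ", "), ": ",
                 paste(unique(head(type_raw[bad], 5)), collapse = ", ")),
          class = "isletgraph_value_error")
  }

  tbl <- tibble::tibble(
    subject_id = as.character(raw[[cols$subject]]),
    group = group,
    islet_id = as.integer(parse_num(raw[[cols$islet]], "islet_id")),
    cell_id = as.integer(parse_num(raw[[cols$cell]], "cell_id")),
    x = parse_num(raw[[cols$x]], "x coordinate"),
    y = parse_num(raw[[cols$y]], "y coordinate"),
    cell_type = unname(dialect$type_map[type_raw])
  )
  if (!is.null(zcol)) {
    tbl$z <- parse_num(raw[[zcol]], "z coordinate")
    tbl <- dplyr::relocate(tbl, "z", .after = "y")
  }
  validate_islet_table(tbl)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Validate an islet table against the schema invariants
#'
#' Checks required columns, finite coordinates, recognised cell types, and
#' uniqueness of the (subject, islet, cell) triple. Called by
#' [read_islet_table()]; exported so programmatically built tables can be
#' checked too.
#'
#' @param tbl A data frame of cell records.
#' @return The table as a tibble, invisibly unchanged, or an error.
#' @export
validate_islet_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  needed <- c("subject_id", "group", "islet_id", "cell_id", "x", "y",
              "cell_type")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "isletgraph_schema_error")
  }
  coord_cols <- intersect(c("x", "y", "z"), names(tbl))
  for (cc in coord_cols) {
    bad <- which(!is.finite(tbl[[cc]]))
    if (length(bad) > 0) {
      abort(paste0("non-finite ", cc, " coordinate at row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "isletgraph_parse_error")
    }
  }
  if (!all(tbl$cell_type %in% CELL_TYPES)) {
    abort("cell_type must be one of alpha, beta, delta",
          class = "isletgraph_value_error")
  }
  if (!all(tbl$group %in% c("control", "t2d"))) {
    abort("group must be 'control' or 't2d'", class = "isletgraph_value_error")
  }
  key <- paste(tbl$subject_id, tbl$islet_id, tbl$cell_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_dup <- tbl[which(dup)[1], ]
    abort(paste0("duplicated (subject, islet, cell) triple: (",
                 first_dup$subject_id, ", ", first_dup$islet_id, ", ",
                 first_dup$cell_id, ")"),
          class = "isletgraph_uniqueness_error")
  }
  one_group <- tbl |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(one_group) > 0) {
    abort(paste0("subject(s) assigned to more than one group: ",
                 paste(one_group$subject_id, collapse = ", ")),
          class = "isletgraph_value_error")
  }
  tbl
}

#' Write an islet table back to delimited text
#'
#' Round-trip companion of [read_islet_table()]: writes one row per cell with
#' the canonical header, so that reading the file back reproduces the table
#' field for field.
#'
#' @param tbl A validated islet table.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_islet_table <- function(tbl, path, delim = ",") {
  tbl <- validate_islet_table(tbl)
  out <- dplyr::select(tbl, -"group")
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Keep only cells of one endocrine type
#'
#' Restricts an islet table to one cell type (by default the insulin-secreting
#' beta cells, the graph vertices of this package). Islets containing no cell
#' of the requested type disappear from the table; their number is attached as
#' attribute `n_dropped_islets` so the reduction is auditable.
#'
#' @param tbl A validated islet table.
#' @param cell_type `"alpha"`, `"beta"` or `"delta"`.
#' @return The filtered tibble with attribute `n_dropped_islets`.
#' @export
filter_cells <- function(tbl, cell_type = "beta") {
  cell_type <- match.arg(cell_type, CELL_TYPES)
  tbl <- tibble::as_tibble(tbl)
  before <- dplyr::n_distinct(paste(tbl$subject_id, tbl$islet_id))
  out <- dplyr::filter(tbl, .data$cell_type == !!cell_type)
  after <- dplyr::n_distinct(paste(out$subject_id, out$islet_id))
  attr(out, "n_dropped_islets") <- before - after
  out
}

#' Summarise cohort composition
#'
#' Per-subject (and per-group) counts of islets and cells, optionally split
#' into large and small islets using the effective-diameter classifier applied
#' to all endocrine cells of each islet (not only beta cells).
#'
#' @param tbl A validated islet table (all cell types).
#' @param split_size Add large/small islet and cell counts?
#' @param size_threshold Effective-diameter threshold in micrometres below
#'   which an islet counts as small.
#' @return A tibble with one row per subject plus one `TOTAL` row per group.
#' @export
summarize_islets <- function(tbl, split_size = TRUE, size_threshold = 60) {
  tbl <- validate_islet_table(tbl)
  per_islet <- tbl |>
    dplyr::group_by(.data$group, .data$subject_id, .data$islet_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      size_class = if (split_size) {
        classify_islet_size(dplyr::pick(dplyr::everything()),
                            threshold = size_threshold)
      } else NA_character_,
      .groups = "drop"
    )
  per_subject <- per_islet |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(
      n_islets = dplyr::n(),
      n_islets_large = sum(.data$size_class == "large"),
      n_islets_small = sum(.data$size_class == "small"),
      n_cells_large = sum(.data$n_cells[.data$size_class == "large"]),
      n_cells_small = sum(.data$n_cells[.data$size_class == "small"]),
      n_cells = sum(.data$n_cells),
      .groups = "drop"
    )
  per_subject <- dplyr::relocate(per_subject, "n_cells",
                                 .after = "n_islets")
  totals <- per_subject |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      subject_id = "TOTAL",
      dplyr::across(dplyr::starts_with("n_"), sum),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(per_subject, totals) |>
    dplyr::arrange(.data$group, .data$subject_id == "TOTAL", .data$subject_id)
  if (!split_size) {
    out <- dplyr::select(out, -dplyr::ends_with("large"),
                         -dplyr::ends_with("small"))
  }
  out
}
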