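#' Read an array-layout table
#'
#' The layout is the single source of truth for array geometry and
#' annotation: it maps every peptide substrate to a grid position
#' (block, row, col; 0-based) and to zero or more upstream-kinase signal
#' categories. Downstream stages inherit their peptide order from the
#' layout, so all writers emit rows in layout order.
#'
#' The file is tab-delimited with a header. Required columns:
#' `peptide_id`, `block`, `row`, `col`. Optional columns:
#' `substrate_seq` (amino-acid string) and `categories`
#' (semicolon-separated labels, possibly empty). Category labels are
#' case-sensitive free-form strings, so a figure's category set is data,
#' not code.
#'
#' @param path Path to a tab-delimited layout file.
#' @return A tibble with one row per peptide and columns `peptide_id`,
#'   `block`, `row`, `col`, `substrate_seq`, and a list-column
#'   `categories` of character vectors (length zero for unannotated
#'   peptides). Row order follows the file.
#' @seealso [default_layout()] for the layout shipped with the package,
#'   [layout_categories()] for a long peptide-to-category table.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "peptide_id\tblock\trow\tcol\tcategories",
#'   "p1\t0\t0\t0\tPAK;mTOR",
#'   "p2\t0\t0\t1\t"
#' ), tf)
#' read_layout(tf)
#' @export
read_layout <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  check_columns(raw, c("peptide_id", "block", "row", "col"), "Layout file")
  layout <- tibble::tibble(
    peptide_id = as.character(raw$peptide_id),
    block = parse_grid_int(raw$block, "block"),
    row = parse_grid_int(raw$row, "row"),
    col = parse_grid_int(raw$col, "col"),
    substrate_seq = if ("substrate_seq" %in% names(raw)) {
      as.character(raw$substrate_seq)
    } else {
      NA_character_
    },
    categories = split_categories(
      if ("categories" %in% names(raw)) raw$categories else ""
    )
  )
  validate_layout(layout)
}

parse_grid_int <- function(x, name) {
  out <- suppressWarnings(as.integer(x))
  if (anyNA(out)) {
    kn_abort(sprintf("Layout column `%s` must contain integers.", name))
  }
  out
}

split_categories <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Validate an array layout
#'
#' Checks the layout invariants: unique non-empty peptide identifiers,
#' at most one peptide per (block, row, col) grid position, and
#' non-negative integer coordinates.
#'
#' @param layout A layout tibble as returned by [read_layout()] or
#'   [make_layout()].
#' @return The layout, invisibly usable in a pipe; errors on violation.
#' @export
validate_layout <- function(layout) {
  check_columns(layout, c("peptide_id", "block", "row", "col", "categories"),
                "Layout")
  ids <- layout$peptide_id
  if (anyNA(ids) || any(!nzchar(ids))) {
    kn_abort("Layout peptide identifiers must be non-empty.")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    kn_abort(sprintf("Duplicate peptide_id in layout: %s.", dup[[1L]]),
             class = "kinomescore_duplicate_id")
  }
  if (any(layout$block < 0L) || any(layout$row < 0L) || any(layout$col < 0L)) {
    kn_abort("Grid coordinates must be non-negative (0-based).")
  }
  grid <- paste(layout$block, layout$row, layout$col)
  if (anyDuplicated(grid)) {
    kn_abort(sprintf("Grid position occupied twice: (%s).",
                     gsub(" ", ",", grid[duplicated(grid)][[1L]])))
  }
  layout
}

#' Category labels present in a layout
#'
#' @param layout A layout tibble.
#' @return Sorted character vector of the distinct category labels
#'   attached to any peptide.
#' @export
category_levels <- function(layout) {
  sort(unique(unlist(layout$categories)))
}

#' Long peptide-to-category table
#'
#' Unnests the layout's `categories` list-column into one row per
#' (peptide, category) pair. Peptides without categories drop out; they
#' are still scored but excluded from category collapse.
#'
#' @param layout A layout tibble.
#' @return A tibble with columns `peptide_id`, `category`.
#' @export
layout_categories <- function(layout) {
  validate_layout(layout)
  out <- tidyr::unnest_longer(
    dplyr::select(layout, "peptide_id", "categories"),
    "categories", values_to = "category"
  )
  dplyr::filter(out, !is.na(.data$category))
}

#' Write a layout table
#'
#' Inverse of [read_layout()]: categories are re-joined with semicolons.
#' Round-trips losslessly.
#'
#' @param layout A layout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  out <- tibble::tibble(
    peptide_id = layout$peptide_id,
    block = layout$block,
    row = layout$row,
    col = layout$col,
    substrate_seq = layout$substrate_seq,
    categories = vapply(layout$categories, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The default 1024-peptide layout
#'
#' Returns the layout shipped with the package: 1024 peptide substrates
#' on a 4-block, 16 x 16 grid with twelve 20-peptide signal categories
#' (mTOR, p70S6K, AMPK, Chk1/Chk2, PAK, PKA, PKC, CK2, GSK3, CDK, Src,
#' CaMK2). The peptide-to-category assignment is synthetic (generated by
#' [make_layout()] under the default configuration), standing in for a
#' proprietary array annotation; the file lives at
#' `system.file("extdata", "synthetic_layout_1024.tsv", package = "kinomescore")`.
#'
#' @return A validated layout tibble with 1024 rows.
#' @export
default_layout <- function() {
  read_layout(default_layout_path())
}

#' @rdname default_layout
#' @export
default_layout_path <- function() {
  system.file("extdata", "synthetic_layout_1024.tsv",
              package = "kinomescore", mustWork = TRUE)
}
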