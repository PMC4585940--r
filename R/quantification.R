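#' Parse a reaction filename
#'
#' Reaction files follow the convention `<condition>_b<k>_t<m>.tsv`,
#' e.g. `KO_b2_t3.tsv` is biological replicate 2, technical replicate 3
#' of condition "KO". The condition label may itself contain
#' underscores; the last two `_b<int>` / `_t<int>` components are
#' grammar.
#'
#' @param path A filename or path; directory and extension are ignored.
#' @return A list with elements `condition` (character), `bio_rep` and
#'   `tech_rep` (integers, both >= 1).
#' @export
parse_reaction_filename <- function(path) {
  name <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(name, regexec("^(.+)_b([0-9]+)_t([0-9]+)$", name))[[1L]]
  if (length(m) != 4L) {
    kn_abort(sprintf(
      "Filename `%s` does not follow the `<condition>_b<k>_t<m>` convention.",
      name
    ))
  }
  out <- list(
    condition = m[[2L]],
    bio_rep = as.integer(m[[3L]]),
    tech_rep = as.integer(m[[4L]])
  )
  if (out$bio_rep < 1L || out$tech_rep < 1L) {
    kn_abort("Replicate indices in a reaction filename must be >= 1.")
  }
  out
}

#' Standard reaction filename for a (condition, bio, tech) triple
#'
#' @param condition Condition label.
#' @param bio_rep,tech_rep Replicate indices (>= 1).
#' @return A filename like `"KO_b2_t3.tsv"`.
#' @export
reaction_filename <- function(condition, bio_rep, tech_rep) {
  sprintf("%s_b%d_t%d.tsv", condition, as.integer(bio_rep),
          as.integer(tech_rep))
}

#' Read a spot-quantification table for one reaction
#'
#' A quantification file holds the grid-tool output for one array
#' reaction: per-spot foreground density and local background density
#' (nonnegative phosphor-imager units), optionally a `flag` column with
#' values `ok` or `bad_spot` (missing flag defaults to `ok`). The column
#' alias `spot_density` is accepted for `foreground_density`.
#'
#' The reaction identity (condition, biological replicate, technical
#' replicate) is taken from the filename convention
#' `<condition>_b<k>_t<m>.tsv` unless supplied explicitly; explicit
#' arguments win.
#'
#' Every layout peptide must appear exactly once; rows are reordered to
#' layout order so downstream numbers never depend on file row order.
#'
#' @param path Path to a tab-delimited quantification file.
#' @param layout The array layout the file must align with.
#' @param condition,bio_rep,tech_rep Optional explicit reaction identity;
#'   any that are `NULL` are parsed from the filename.
#' @return A tibble with columns `condition`, `bio_rep`, `tech_rep`,
#'   `peptide_id`, `foreground_density`, `background_density`, `flag`,
#'   in layout order.
#' @export
read_quantification <- function(path, layout, condition = NULL,
                                bio_rep = NULL, tech_rep = NULL) {
  validate_layout(layout)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"foreground_density" %in% names(raw) && "spot_density" %in% names(raw)) {
    names(raw)[names(raw) == "spot_density"] <- "foreground_density"
  }
  check_columns(raw, c("peptide_id", "foreground_density", "background_density"),
                "Quantification file")

  if (is.null(condition) || is.null(bio_rep) || is.null(tech_rep)) {
    parsed <- parse_reaction_filename(path)
    condition <- condition %||% parsed$condition
    bio_rep <- bio_rep %||% parsed$bio_rep
    tech_rep <- tech_rep %||% parsed$tech_rep
  }
  check_number(bio_rep, "bio_rep", min = 1, integer = TRUE)
  check_number(tech_rep, "tech_rep", min = 1, integer = TRUE)

  quant <- tibble::tibble(
    condition = as.character(condition),
    bio_rep = as.integer(bio_rep),
    tech_rep = as.integer(tech_rep),
    peptide_id = as.character(raw$peptide_id),
    foreground_density = parse_density(raw$foreground_density,
                                       "foreground_density"),
    background_density = parse_density(raw$background_density,
                                       "background_density"),
    flag = if ("flag" %in% names(raw)) as.character(raw$flag) else "ok"
  )
  quant$flag[is.na(quant$flag) | !nzchar(quant$flag)] <- "ok"
  bad_flag <- setdiff(unique(quant$flag), c("ok", "bad_spot"))
  if (length(bad_flag) > 0L) {
    kn_abort(sprintf("Unknown spot flag `%s` (expected ok or bad_spot).",
                     bad_flag[[1L]]))
  }
  align_to_layout(quant, layout)
}

parse_density <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) || any(!is.finite(out))) {
    kn_abort(sprintf("Column `%s` must contain finite numbers.", name))
  }
  if (any(out < 0)) {
    kn_abort(sprintf("Column `%s` contains negative densities.", name))
  }
  out
}

align_to_layout <- function(quant, layout) {
  dup <- quant$peptide_id[duplicated(quant$peptide_id)]
  if (length(dup) > 0L) {
    kn_abort(sprintf("Peptide `%s` appears more than once in quantification.",
                     dup[[1L]]))
  }
  extra <- setdiff(quant$peptide_id, layout$peptide_id)
  if (length(extra) > 0L) {
    kn_abort(sprintf("Peptide `%s` in quantification is absent from layout.",
                     extra[[1L]]))
  }
  missing <- setdiff(layout$peptide_id, quant$peptide_id)
  if (length(missing) > 0L) {
    kn_abort(sprintf("Layout peptide `%s` is missing from quantification.",
                     missing[[1L]]))
  }
  quant[match(layout$peptide_id, quant$peptide_id), , drop = FALSE]
}

#' Write one reaction's quantification table
#'
#' Emits the file dialect read by [read_quantification()]
#' (`peptide_id`, `foreground_density`, `background_density`, `flag`) in
#' the row order given (layout order by construction), so writes are
#' bit-reproducible.
#'
#' @param quant A single-reaction quantification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantification <- function(quant, path) {
  check_columns(quant, c("peptide_id", "foreground_density",
                         "background_density", "flag"),
                "Quantification")
  if (dplyr::n_distinct(reaction_key(quant$condition, quant$bio_rep,
                                     quant$tech_rep)) != 1L) {
    kn_abort("write_quantification() expects exactly one reaction.")
  }
  readr::write_tsv(
    dplyr::select(quant, "peptide_id", "foreground_density",
                  "background_density", "flag"),
    path, progress = FALSE
  )
  invisible(path)
}
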