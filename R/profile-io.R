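#' Write and read kinome profiles
#'
#' A kinome profile holds one condition's per-peptide Markov scores: the
#' number of reactions (out of `R` = biological x technical replicates)
#' in which the peptide was called significantly phosphorylated, plus
#' `n_called`, the number of reactions that yielded a usable call
#' (flagged bad spots give no call). The file is tab-delimited with
#' columns `condition`, `peptide_id`, `markov_score`, `n_called`, `R`
#' and round-trips losslessly through `read_profile()`.
#'
#' @param profile A profile tibble as returned by [markov_scores()].
#' @param path Output (or input) path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a validated profile tibble.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  readr::write_tsv(
    dplyr::select(profile, "condition", "peptide_id", "markov_score",
                  "n_called", "R"),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  profile <- readr::read_tsv(
    path,
    col_types = readr::cols(
      condition = readr::col_character(),
      peptide_id = readr::col_character(),
      markov_score = readr::col_integer(),
      n_called = readr::col_integer(),
      R = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_profile(profile)
}

validate_profile <- function(profile) {
  check_columns(profile, c("condition", "peptide_id", "markov_score",
                           "n_called", "R"), "Profile")
  if (nrow(profile) == 0L) {
    return(profile)
  }
  dup <- paste(profile$condition, profile$peptide_id)
  if (anyDuplicated(dup)) {
    kn_abort("Profile contains a duplicated (condition, peptide) pair.")
  }
  bad <- profile$markov_score < 0L |
    profile$markov_score > profile$n_called |
    profile$n_called > profile$R
  if (any(bad)) {
    kn_abort(sprintf(
      "Profile violates 0 <= markov_score <= n_called <= R for peptide `%s`.",
      profile$peptide_id[bad][[1L]]
    ))
  }
  profile
}
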