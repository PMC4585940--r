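#' Aggregate per-reaction calls into Markov scores
#'
#' The Markov score of a peptide in a condition is the number of
#' reactions (out of `R` = biological x technical replicates, 6 in the
#' default design) in which it was called significantly phosphorylated
#' above background — an integer between 0 (never) and `R` (in every
#' reaction). `n_called` counts the reactions that produced a usable
#' call; `no_call` reactions (bad spots) shrink it, so
#' `0 <= markov_score <= n_called <= R` always holds.
#'
#' @param calls Calls tibble from [call_phosphostates()] (one or more
#'   conditions; each reaction must appear exactly once per condition).
#' @param layout The array layout; output rows follow layout order.
#' @param R Total reactions per condition; defaults to the number of
#'   distinct reactions observed per condition.
#' @return A profile tibble: `condition`, `peptide_id`, `markov_score`,
#'   `n_called`, `R`.
#' @export
markov_scores <- function(calls, layout, R = NULL) {
  validate_layout(layout)
  check_columns(calls, c("condition", "bio_rep", "tech_rep", "peptide_id",
                         "state"), "Calls")
  out <- lapply(split(calls, calls$condition), function(cc) {
    rxn <- dplyr::distinct(cc, .data$bio_rep, .data$tech_rep)
    key <- reaction_key(cc$condition, cc$bio_rep, cc$tech_rep)
    per_rxn <- table(key) / length(unique(cc$peptide_id))
    if (nrow(rxn) * length(unique(cc$peptide_id)) != nrow(cc)) {
      kn_abort(sprintf(
        "Condition `%s` has a duplicated (bio_rep, tech_rep) reaction or misaligned peptides.",
        cc$condition[[1L]]
      ))
    }
    R_c <- R %||% nrow(rxn)
    check_number(R_c, "R", min = nrow(rxn), integer = TRUE)
    scored <- cc |>
      dplyr::group_by(.data$peptide_id) |>
      dplyr::summarise(
        markov_score = sum(.data$state == "phosphorylated"),
        n_called = sum(.data$state != "no_call"),
        .groups = "drop"
      )
    scored <- scored[match(layout$peptide_id, scored$peptide_id), ,
                     drop = FALSE]
    if (anyNA(scored$peptide_id)) {
      kn_abort("Calls do not cover every layout peptide.")
    }
    tibble::tibble(
      condition = cc$condition[[1L]],
      peptide_id = scored$peptide_id,
      markov_score = as.integer(scored$markov_score),
      n_called = as.integer(scored$n_called),
      R = as.integer(R_c)
    )
  })
  validate_profile(dplyr::bind_rows(out))
}

#' Collapse Markov scores onto signal categories
#'
#' For each signal category and condition, computes the fraction
#' `f_c` of member peptides counted phosphorylated, i.e. with Markov
#' score at least `tau` — the grey-scale quantity used to compare
#' pathway-level signaling between conditions. Uncategorized peptides
#' are excluded; peptides whose `n_called` fell below `R / 2` are
#' dropped (with a message) since a score supported by too few
#' reactions is uninterpretable.
#'
#' `tau` defaults to 4 of 6: phosphorylated in a majority of reactions.
#' `tau = 1` instead reads "phosphorylated in any reaction".
#'
#' @param profile Profile tibble from [markov_scores()] (one or more
#'   conditions).
#' @param layout The array layout carrying category annotations.
#' @param tau Markov-score call threshold, integer in `[1, R]`.
#' @return A tibble `condition`, `category`, `n` (member peptides
#'   retained), `n_phospho`, `fraction`.
#' @export
category_fractions <- function(profile, layout, tau = 4) {
  validate_profile(profile)
  validate_layout(layout)
  if (nrow(profile) > 0L) {
    check_number(tau, "tau", min = 1, max = max(profile$R), integer = TRUE)
  }
  kept <- dplyr::filter(profile, .data$n_called >= .data$R / 2)
  dropped <- nrow(profile) - nrow(kept)
  if (dropped > 0L) {
    inform(sprintf(
      "Dropped %d peptide record%s with n_called < R/2 from category fractions.",
      dropped, if (dropped > 1L) "s" else ""
    ))
  }
  cats <- layout_categories(layout)
  dplyr::inner_join(kept, cats, by = "peptide_id",
                    relationship = "many-to-many") |>
    dplyr::group_by(.data$condition, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_phospho = sum(.data$markov_score >= tau),
      fraction = .data$n_phospho / .data$n,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition, .data$category)
}
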