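#' Background-correct spot densities
#'
#' Subtracts each spot's local background from its foreground density,
#' flooring at zero (a spot cannot be less phosphorylated than nothing).
#' Spots flagged `bad_spot` get `NA` corrected values and are excluded
#' from model fitting and calling downstream.
#'
#' @param quant Quantification tibble (any number of reactions).
#' @return The input with a `corrected` column appended.
#' @export
correct_background <- function(quant) {
  check_columns(quant, c("peptide_id", "foreground_density",
                         "background_density", "flag"),
                "Quantification")
  dplyr::mutate(
    quant,
    corrected = dplyr::if_else(
      .data$flag == "bad_spot",
      NA_real_,
      pmax(.data$foreground_density - .data$background_density, 0)
    )
  )
}

#' Call per-peptide phosphorylation states for one reaction
#'
#' Applies a fitted two-state model to background-corrected densities:
#' a peptide is `phosphorylated` when its posterior reaches `threshold`
#' (a posterior exactly at the threshold counts as phosphorylated, so
#' the pipeline is deterministic), `background` otherwise, and `no_call`
#' when its spot was flagged bad.
#'
#' @param corrected_quant Output of [correct_background()] for a single
#'   reaction (must contain `corrected` and `flag`).
#' @param model A `two_state_model` fitted to this reaction.
#' @param threshold Posterior decision threshold in `[0, 1]`
#'   (default 0.5).
#' @return The input tibble with `posterior` and `state` columns.
#' @export
call_states <- function(corrected_quant, model, threshold = 0.5) {
  check_columns(corrected_quant, c("peptide_id", "corrected", "flag"),
                "Corrected quantification")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0 || threshold > 1) {
    kn_abort("`threshold` must be in [0, 1].")
  }
  posterior <- posterior_phospho(model, corrected_quant$corrected)
  dplyr::mutate(
    corrected_quant,
    posterior = posterior,
    state = dplyr::case_when(
      .data$flag == "bad_spot" ~ "no_call",
      posterior >= threshold ~ "phosphorylated",
      TRUE ~ "background"
    )
  )
}

#' Call phosphorylation states across all reactions of a study
#'
#' The per-reaction driver for the calling stage: for every
#' (condition, biological, technical) reaction independently, corrects
#' background, fits the two-state mixture ([fit_two_state()]) and calls
#' states ([call_states()]). No information is pooled across replicates
#' before scoring. A robust z-score rule
#' (`corrected > median + k * MAD`) is available as `method = "zscore"`
#' for degenerate data where a mixture is not identifiable; its calls
#' carry pseudo-posteriors 0/1.
#'
#' @param quant Long quantification tibble covering whole study.
#' @param method `"mixture"` (default) or `"zscore"`.
#' @param threshold Posterior decision threshold for the mixture method.
#' @param zscore_k MAD multiplier for the z-score method (default 3).
#' @return A calls tibble (`condition`, `bio_rep`, `tech_rep`,
#'   `peptide_id`, `corrected`, `posterior`, `state`) with the per-
#'   reaction fitted models attached as attribute `"models"` (a named
#'   list; `NULL` entries for the z-score method).
#' @export
call_phosphostates <- function(quant, method = c("mixture", "zscore"),
                               threshold = 0.5, zscore_k = 3) {
  method <- match.arg(method)
  check_number(zscore_k, "zscore_k", min = 0)
  reactions <- dplyr::group_split(quant, .data$condition, .data$bio_rep,
                                  .data$tech_rep)
  models <- list()
  calls <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    cq <- correct_background(reactions[[i]])
    key <- reaction_filename(cq$condition[[1L]], cq$bio_rep[[1L]],
                             cq$tech_rep[[1L]])
    if (method == "mixture") {
      model <- fit_two_state(cq$corrected)
      called <- call_states(cq, model, threshold = threshold)
      models[[key]] <- model
    } else {
      called <- call_zscore(cq, k = zscore_k)
      models[key] <- list(NULL)
    }
    calls[[i]] <- dplyr::select(
      called, "condition", "bio_rep", "tech_rep", "peptide_id",
      "corrected", "posterior", "state"
    )
  }
  out <- dplyr::bind_rows(calls)
  attr(out, "models") <- models
  out
}

call_zscore <- function(corrected_quant, k = 3) {
  x <- corrected_quant$corrected
  cutoff <- median(x, na.rm = TRUE) + k * mad(x, na.rm = TRUE)
  called <- !is.na(x) & x > cutoff
  dplyr::mutate(
    corrected_quant,
    posterior = dplyr::if_else(is.na(x), NA_real_, as.numeric(called)),
    state = dplyr::case_when(
      .data$flag == "bad_spot" ~ "no_call",
      called ~ "phosphorylated",
      TRUE ~ "background"
    )
  )
}
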