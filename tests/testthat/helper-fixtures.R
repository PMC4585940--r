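# Small programmatic fixtures shared across test files.

tiny_layout <- function(n = 4L, categories = NULL) {
  layout <- tibble::tibble(
    peptide_id = paste0("p", seq_len(n)),
    block = 0L,
    row = (seq_len(n) - 1L) %/% 4L,
    col = (seq_len(n) - 1L) %% 4L,
    substrate_seq = NA_character_,
    categories = categories %||% rep(list(character(0)), n)
  )
  validate_layout(layout)
}

write_tiny_quant <- function(path, ids, fg, bg, flag = NULL, header = NULL) {
  header <- header %||% c("peptide_id", "foreground_density",
                          "background_density", if (!is.null(flag)) "flag")
  rows <- if (is.null(flag)) {
    paste(ids, fg, bg, sep = "\t")
  } else {
    paste(ids, fg, bg, flag, sep = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

# one-reaction quantification tibble built in memory
make_quant <- function(ids, fg, bg, flag = "ok", condition = "WT",
                       bio_rep = 1L, tech_rep = 1L) {
  tibble::tibble(
    condition = condition, bio_rep = bio_rep, tech_rep = tech_rep,
    peptide_id = ids,
    foreground_density = fg,
    background_density = bg,
    flag = rep_len(flag, length(ids))
  )
}

# calls tibble for one condition from a peptide x reaction state matrix
# (entries "P", "B", "N")
make_calls <- function(states, condition = "X") {
  n_rxn <- ncol(states)
  ids <- rownames(states) %||% paste0("p", seq_len(nrow(states)))
  reps <- expand.grid(tech_rep = 1:3, bio_rep = 1:((n_rxn + 2) %/% 3))
  reps <- reps[seq_len(n_rxn), ]
  out <- list()
  for (j in seq_len(n_rxn)) {
    out[[j]] <- tibble::tibble(
      condition = condition,
      bio_rep = reps$bio_rep[j],
      tech_rep = reps$tech_rep[j],
      peptide_id = ids,
      corrected = 0,
      posterior = NA_real_,
      state = c(P = "phosphorylated", B = "background",
                N = "no_call")[states[, j]]
    )
  }
  dplyr::bind_rows(out)
}

# small two-condition study configuration for fast end-to-end tests
small_config <- function(seed = 1L, multipliers = "default", ...) {
  mult <- if (identical(multipliers, "default")) {
    tibble::tibble(condition = "KO", category = c("mTOR", "PAK"),
                   multiplier = 4)
  } else {
    multipliers
  }
  generation_config(
    n_peptides = 128L,
    category_spec = c(mTOR = 10L, PAK = 10L, PKA = 10L, CK2 = 10L),
    activity_multipliers = mult,
    seed = seed,
    ...
  )
}
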