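# internal helpers: error signalling and small validators

kn_abort <- function(message, class = "kinomescore_error", ...) {
  rlang::abort(message, class = unique(c(class, "kinomescore_error")), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    kn_abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    kn_abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (integer && x != trunc(x)) {
    kn_abort(sprintf("`%s` must be an integer.", name))
  }
  if (x < min || x > max) {
    kn_abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    kn_abort(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ), class = "kinomescore_missing_column")
  }
  invisible(df)
}

# reaction key used for grouping / duplicate detection
reaction_key <- function(condition, bio_rep, tech_rep) {
  paste0(condition, "\r_b", bio_rep, "_t", tech_rep)
}
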