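#' Differential category signaling between two conditions
#'
#' Quantifies the per-category contrast between two kinome profiles.
#' For each signal category the statistic is the absolute difference in
#' phosphorylated fractions, `|delta|` with
#' `delta = f_b - f_a` and `f = #(markov_score >= tau) / n` over member
#' peptides. Significance comes from a label-permutation null: category
#' memberships are randomly reassigned over all categorized peptides
#' (preserving category sizes) `n_perm` times, `|delta|` is recomputed
#' each time, and `p = (1 + #(null >= observed)) / (1 + n_perm)` (the
#' add-one estimator, so p is never zero). p-values are
#' Benjamini-Hochberg adjusted across categories. Deterministic given
#' `seed`.
#'
#' Peptides must have `n_called >= R / 2` in both profiles to enter;
#' only peptides carrying at least one category participate in the
#' permutation pool.
#'
#' @param profile_a,profile_b Single-condition profile tibbles from
#'   [markov_scores()] on the same layout (same peptides, same `R`).
#'   `delta > 0` means the category is more phosphorylated in
#'   `profile_b`.
#' @param layout The shared array layout.
#' @param tau Markov-score call threshold (default 4).
#' @param n_perm Number of membership permutations (default 10000; a
#'   value below 100 triggers a warning).
#' @param seed Integer seed for the permutation draw.
#' @return A `differential_categories` tibble: `category`, `n`, `f_a`,
#'   `f_b`, `delta`, `p_value`, `q_value`, with the condition labels,
#'   `tau` and `n_perm` as attributes.
#' @export
differential_categories <- function(profile_a, profile_b, layout,
                                    tau = 4, n_perm = 10000, seed = 1L) {
  validate_profile(profile_a)
  validate_profile(profile_b)
  validate_layout(layout)
  check_number(n_perm, "n_perm", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (n_perm < 100) {
    warn("`n_perm` < 100 gives very coarse permutation p-values.")
  }
  if (dplyr::n_distinct(profile_a$condition) != 1L ||
      dplyr::n_distinct(profile_b$condition) != 1L) {
    kn_abort("Each profile must hold exactly one condition.")
  }
  if (!setequal(profile_a$peptide_id, layout$peptide_id) ||
      !setequal(profile_b$peptide_id, layout$peptide_id) ||
      profile_a$R[[1L]] != profile_b$R[[1L]]) {
    kn_abort("Profiles must share the layout's peptides and the same R.")
  }
  R <- profile_a$R[[1L]]
  check_number(tau, "tau", min = 1, max = R, integer = TRUE)

  a <- profile_a[match(layout$peptide_id, profile_a$peptide_id), ]
  b <- profile_b[match(layout$peptide_id, profile_b$peptide_id), ]
  keep <- a$n_called >= R / 2 & b$n_called >= R / 2
  cats <- layout_categories(layout)
  cats <- cats[cats$peptide_id %in% layout$peptide_id[keep], , drop = FALSE]
  if (nrow(cats) == 0L) {
    kn_abort("No categorized peptides available for a differential comparison.")
  }

  d <- (b$markov_score >= tau) - (a$markov_score >= tau)
  called_a <- as.numeric(a$markov_score >= tau)
  called_b <- as.numeric(b$markov_score >= tau)
  i <- match(cats$peptide_id, layout$peptide_id)
  member_d <- d[i]
  labels <- factor(cats$category)
  n_c <- as.vector(table(labels))
  lev <- levels(labels)

  obs_delta <- as.vector(rowsum(member_d, labels)) / n_c
  f_a <- as.vector(rowsum(called_a[i], labels)) / n_c
  f_b <- as.vector(rowsum(called_b[i], labels)) / n_c
  obs_abs <- abs(obs_delta)

  exceed <- withr::with_seed(seed, {
    count <- integer(length(lev))
    n_pool <- length(member_d)
    for (k in seq_len(n_perm)) {
      null_delta <- as.vector(
        rowsum(member_d[sample.int(n_pool)], labels)
      ) / n_c
      count <- count + (abs(null_delta) >= obs_abs)
    }
    count
  })
  p <- (1 + exceed) / (1 + n_perm)
  out <- tibble::tibble(
    category = lev,
    n = n_c,
    f_a = f_a,
    f_b = f_b,
    delta = obs_delta,
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
  structure(
    out,
    class = c("differential_categories", class(out)),
    condition_a = a$condition[[1L]],
    condition_b = b$condition[[1L]],
    tau = tau,
    n_perm = n_perm
  )
}

#' Grey-scale fraction matrix of a differential table
#'
#' The category-by-condition matrix of phosphorylated fractions (values
#' in `[0, 1]`), the tabular mirror of a grey-scale category figure.
#'
#' @param diff A `differential_categories` table.
#' @return A tibble `category`, one column per condition.
#' @export
fraction_matrix <- function(diff) {
  stopifnot(inherits(diff, "differential_categories"))
  out <- tibble::tibble(
    category = diff$category,
    a = diff$f_a,
    b = diff$f_b
  )
  names(out)[2:3] <- c(attr(diff, "condition_a"), attr(diff, "condition_b"))
  out
}

#' @method glance differential_categories
#' @export
glance.differential_categories <- function(x, ...) {
  tibble::tibble(
    condition_a = attr(x, "condition_a"),
    condition_b = attr(x, "condition_b"),
    tau = attr(x, "tau"),
    n_perm = attr(x, "n_perm"),
    n_categories = nrow(x),
    n_significant = sum(x$q_value < 0.05)
  )
}

#' @describeIn differential_categories Grey-scale tile plot of
#'   per-category phosphorylated fractions in the two conditions.
#' @param object A `differential_categories` table.
#' @param ... Unused.
#' @method autoplot differential_categories
#' @export
autoplot.differential_categories <- function(object, ...) {
  fm <- fraction_matrix(object)
  long <- tidyr::pivot_longer(fm, -"category", names_to = "condition",
                              values_to = "fraction")
  long$condition <- factor(long$condition,
                           levels = c(attr(object, "condition_a"),
                                      attr(object, "condition_b")))
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$category,
                                     fill = .data$fraction)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fraction\nphosphorylated") +
    ggplot2::theme_minimal()
}
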