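#' Replicate-concordance quality control
#'
#' Computes every within-condition pairwise Pearson product-moment
#' correlation of `log1p(foreground_density)` between reactions, over
#' the peptides flagged `ok` in both members of a pair. Pairs sharing a
#' biological replicate are "technical" comparisons, pairs differing in
#' biological replicate are "biological" comparisons; their means are
#' the quantities gated by [qc_gate()]. Correlations precede background
#' correction and calling, mirroring how array QC is reported.
#'
#' A pair with fewer than 3 shared ok spots has no defined correlation;
#' it is excluded with a warning. If every pair of a condition is
#' undefined, that is a hard error.
#'
#' @param quant Long quantification tibble covering one or more
#'   conditions (e.g. `simulate_study(cfg)$quantifications`).
#' @param threshold Default gate threshold recorded in the report
#'   (see [qc_gate()]).
#' @return A `correlation_report`: list with `pairs` (tibble of every
#'   within-condition pair: replicate indices, `n_spots`, `r`,
#'   `comparison`), `summary` (per condition: `mean_technical_r`,
#'   `mean_biological_r`, `pass`), and `threshold`.
#' @export
replicate_correlations <- function(quant, threshold = 0.85) {
  check_columns(quant, c("condition", "bio_rep", "tech_rep", "peptide_id",
                         "foreground_density", "flag"),
                "Quantification")
  pairs <- dplyr::bind_rows(lapply(
    split(quant, quant$condition),
    condition_pairs
  ))
  if (all(is.na(pairs$r))) {
    kn_abort("No replicate pair has enough shared ok spots for QC.")
  }
  summary <- pairs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_technical_r = mean(.data$r[.data$comparison == "technical"],
                              na.rm = TRUE),
      mean_biological_r = mean(.data$r[.data$comparison == "biological"],
                               na.rm = TRUE),
      .groups = "drop"
    )
  report <- structure(
    list(pairs = pairs, summary = summary, threshold = threshold),
    class = "correlation_report"
  )
  report$summary$pass <- condition_pass(report, threshold)
  report
}

condition_pairs <- function(quant) {
  cond <- quant$condition[[1L]]
  reactions <- quant |>
    dplyr::distinct(.data$bio_rep, .data$tech_rep) |>
    dplyr::arrange(.data$bio_rep, .data$tech_rep)
  if (nrow(reactions) < 2L) {
    kn_abort(sprintf("Condition `%s` has fewer than 2 reactions; QC needs pairs.",
                     cond))
  }
  split_q <- split(quant, reaction_key(quant$condition, quant$bio_rep,
                                       quant$tech_rep))
  keys <- reaction_key(cond, reactions$bio_rep, reactions$tech_rep)
  idx <- combn(nrow(reactions), 2L)
  out <- vector("list", ncol(idx))
  for (j in seq_len(ncol(idx))) {
    a <- split_q[[keys[idx[1L, j]]]]
    b <- split_q[[keys[idx[2L, j]]]]
    b <- b[match(a$peptide_id, b$peptide_id), , drop = FALSE]
    ok <- a$flag == "ok" & b$flag == "ok"
    r <- if (sum(ok) < 3L) {
      warn(sprintf(
        "Pair b%d_t%d vs b%d_t%d in `%s` has %d shared ok spots; correlation undefined.",
        reactions$bio_rep[idx[1L, j]], reactions$tech_rep[idx[1L, j]],
        reactions$bio_rep[idx[2L, j]], reactions$tech_rep[idx[2L, j]],
        cond, sum(ok)
      ))
      NA_real_
    } else {
      cor(log1p(a$foreground_density[ok]), log1p(b$foreground_density[ok]))
    }
    out[[j]] <- tibble::tibble(
      condition = cond,
      bio_a = reactions$bio_rep[idx[1L, j]],
      tech_a = reactions$tech_rep[idx[1L, j]],
      bio_b = reactions$bio_rep[idx[2L, j]],
      tech_b = reactions$tech_rep[idx[2L, j]],
      n_spots = sum(ok),
      r = r,
      comparison = ifelse(reactions$bio_rep[idx[1L, j]] ==
                            reactions$bio_rep[idx[2L, j]],
                          "technical", "biological")
    )
  }
  dplyr::bind_rows(out)
}

condition_pass <- function(report, threshold) {
  s <- report$summary
  # a design without biological pairs (n_bio = 1) is gated on technical r only
  worst <- pmin(s$mean_technical_r,
                ifelse(is.nan(s$mean_biological_r), Inf, s$mean_biological_r))
  worst <- ifelse(is.nan(worst), -Inf, worst)
  worst >= threshold
}

#' Gate a study on replicate concordance
#'
#' Passes when, for every condition, both the mean technical and the
#' mean biological Pearson correlation reach `threshold` (default 0.85,
#' the conventional concordance floor for these arrays). The pipeline
#' refuses to score a study that fails the gate unless explicitly
#' overridden ([run_all()]'s `override_qc`).
#'
#' @param report A `correlation_report` from [replicate_correlations()].
#' @param threshold Pass threshold in (0, 1].
#' @return A single logical: `TRUE` if every condition passes.
#' @export
qc_gate <- function(report, threshold = 0.85) {
  stopifnot(inherits(report, "correlation_report"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1) {
    kn_abort("`threshold` must be in (0, 1].")
  }
  all(condition_pass(report, threshold))
}

#' Pairwise correlation matrix for one condition
#'
#' Assembles the symmetric unit-diagonal matrix of pairwise Pearson
#' correlations for one condition, rows/columns labelled `b<k>_t<m>`.
#'
#' @param report A `correlation_report`.
#' @param condition Condition label; defaults to the first in the report.
#' @return A numeric matrix.
#' @export
cor_matrix <- function(report, condition = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  condition <- condition %||% report$summary$condition[[1L]]
  p <- dplyr::filter(report$pairs, .data$condition == !!condition)
  if (nrow(p) == 0L) {
    kn_abort(sprintf("No QC pairs for condition `%s`.", condition))
  }
  labs <- unique(c(sprintf("b%d_t%d", p$bio_a, p$tech_a),
                   sprintf("b%d_t%d", p$bio_b, p$tech_b)))
  labs <- labs[order(labs)]
  m <- diag(1, length(labs))
  dimnames(m) <- list(labs, labs)
  ia <- match(sprintf("b%d_t%d", p$bio_a, p$tech_a), labs)
  ib <- match(sprintf("b%d_t%d", p$bio_b, p$tech_b), labs)
  m[cbind(ia, ib)] <- p$r
  m[cbind(ib, ia)] <- p$r
  m
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) {
  x$pairs
}

#' @method glance correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  dplyr::mutate(x$summary, threshold = x$threshold)
}

#' @describeIn replicate_correlations Heatmap of the pairwise
#'   correlations, one facet per condition.
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  p <- object$pairs
  long <- dplyr::bind_rows(
    dplyr::transmute(p, .data$condition,
                     a = sprintf("b%d_t%d", .data$bio_a, .data$tech_a),
                     b = sprintf("b%d_t%d", .data$bio_b, .data$tech_b),
                     r = .data$r),
    dplyr::transmute(p, .data$condition,
                     a = sprintf("b%d_t%d", .data$bio_b, .data$tech_b),
                     b = sprintf("b%d_t%d", .data$bio_a, .data$tech_a),
                     r = .data$r)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
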