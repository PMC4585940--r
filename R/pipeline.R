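#' Configuration for a full pipeline run
#'
#' Collects the inputs and tuning parameters of an end-to-end run:
#' either a directory of quantification files plus a layout, or a
#' [generation_config()] to simulate a study in place of file inputs.
#'
#' @param outdir Output directory for all run artifacts.
#' @param layout_path Path to a layout TSV (ignored when `simulate` is
#'   given).
#' @param quant_paths Character vector of reaction quantification files
#'   named `<condition>_b<k>_t<m>.tsv` (ignored when `simulate` is
#'   given).
#' @param simulate Optional [generation_config()]; when supplied the
#'   study is simulated and its files written under
#'   `file.path(outdir, "input")`.
#' @param qc_threshold Replicate-concordance gate (default 0.85).
#' @param call_method,call_threshold,zscore_k Calling parameters, see
#'   [call_phosphostates()].
#' @param tau Markov-score call threshold for category collapse.
#' @param n_perm Permutations for the differential test.
#' @param seed Global seed; stage substreams use fixed offsets
#'   (simulation uses the seed itself, the permutation test `seed + 1`)
#'   so stage reruns agree with full runs.
#' @param override_qc Proceed to scoring even if QC fails.
#' @return A validated `run_config` object.
#' @export
run_config <- function(outdir,
                       layout_path = NULL,
                       quant_paths = NULL,
                       simulate = NULL,
                       qc_threshold = 0.85,
                       call_method = "mixture",
                       call_threshold = 0.5,
                       zscore_k = 3,
                       tau = 4,
                       n_perm = 10000,
                       seed = 1L,
                       override_qc = FALSE) {
  if (is.null(simulate) && (is.null(layout_path) || is.null(quant_paths))) {
    kn_abort("Provide either `simulate` or both `layout_path` and `quant_paths`.")
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "generation_config"))
  }
  if (qc_threshold <= 0 || qc_threshold > 1) {
    kn_abort("`qc_threshold` must be in (0, 1].")
  }
  call_method <- match.arg(call_method, c("mixture", "zscore"))
  check_number(call_threshold, "call_threshold", min = 0, max = 1)
  check_number(tau, "tau", min = 1, integer = TRUE)
  check_number(n_perm, "n_perm", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      outdir = outdir, layout_path = layout_path, quant_paths = quant_paths,
      simulate = simulate, qc_threshold = qc_threshold,
      call_method = call_method, call_threshold = call_threshold,
      zscore_k = zscore_k, tau = as.integer(tau),
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      override_qc = isTRUE(override_qc)
    ),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Orchestrates simulate/read -> QC -> calling -> Markov scoring ->
#' category collapse -> differential comparison as one reproducible
#' run. Every stage writes its output to `outdir` so each stage is
#' independently re-runnable from files, and a `manifest.json` records
#' the configuration, seed, package version and MD5 checksums of all
#' inputs and outputs. Rerunning with the same configuration reproduces
#' byte-identical artifacts.
#'
#' Statuses mirror command-line exit codes: 0 = success, 3 = QC gate
#' failed without `override_qc` (no scoring outputs are written).
#' Validation problems raise errors (exit code 2 in the CLI wrapper).
#'
#' @param config A [run_config()].
#' @return A list with `status`, `outdir`, `files` (named paths),
#'   `qc` (the correlation report) and, on success, `differential`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  input_files <- character(0)

  if (!is.null(config$simulate)) {
    sim_cfg <- unclass(config$simulate)
    sim_cfg$seed <- config$seed
    study <- simulate_study(do.call(generation_config, sim_cfg))
    input_dir <- file.path(outdir, "input")
    input_files <- write_study(study, input_dir)
    layout <- study$layout
    quant <- study$quantifications
  } else {
    input_files <- c(config$layout_path, config$quant_paths)
    layout <- read_layout(config$layout_path)
    quant <- dplyr::bind_rows(
      lapply(config$quant_paths, read_quantification, layout = layout)
    )
  }

  report <- replicate_correlations(quant, threshold = config$qc_threshold)
  files["correlations"] <- file.path(outdir, "correlations.tsv")
  readr::write_tsv(tidy(report), files[["correlations"]], progress = FALSE)
  files["qc_summary"] <- file.path(outdir, "qc_summary.json")
  jsonlite::write_json(glance(report), files[["qc_summary"]],
                       dataframe = "rows", pretty = TRUE, digits = NA)

  passed <- qc_gate(report, config$qc_threshold)
  if (!passed && !config$override_qc) {
    manifest <- write_manifest(config, input_files, files, outdir,
                               status = 3L)
    inform("QC gate failed; scoring stages skipped (set override_qc to force).")
    return(list(status = 3L, outdir = outdir, files = files, qc = report,
                manifest = manifest))
  }

  calls <- call_phosphostates(quant, method = config$call_method,
                              threshold = config$call_threshold,
                              zscore_k = config$zscore_k)
  for (cc in split(calls, calls$condition)) {
    for (rxn in dplyr::group_split(cc, .data$bio_rep, .data$tech_rep)) {
      key <- sprintf("calls_%s_b%d_t%d", rxn$condition[[1L]],
                     rxn$bio_rep[[1L]], rxn$tech_rep[[1L]])
      files[key] <- file.path(outdir, paste0(key, ".tsv"))
      readr::write_tsv(
        dplyr::select(rxn, "peptide_id", "corrected", "posterior", "state"),
        files[[key]], progress = FALSE
      )
    }
  }

  profile <- markov_scores(calls, layout)
  # reference condition = first seen in the inputs, not alphabetical
  conditions <- unique(quant$condition)
  for (cond in conditions) {
    key <- paste0("profile_", cond)
    files[key] <- file.path(outdir, paste0(key, ".tsv"))
    write_profile(dplyr::filter(profile, .data$condition == cond),
                  files[[key]])
  }
  fractions <- category_fractions(profile, layout, tau = config$tau)
  files["category_fractions"] <- file.path(outdir, "category_fractions.tsv")
  readr::write_tsv(fractions, files[["category_fractions"]], progress = FALSE)

  diff <- NULL
  if (length(conditions) == 2L) {
    diff <- differential_categories(
      dplyr::filter(profile, .data$condition == conditions[[1L]]),
      dplyr::filter(profile, .data$condition == conditions[[2L]]),
      layout, tau = config$tau, n_perm = config$n_perm,
      seed = config$seed + 1L
    )
    files["differential"] <- file.path(outdir, "differential.tsv")
    readr::write_tsv(tibble::as_tibble(diff), files[["differential"]],
                     progress = FALSE)
    files["fraction_matrix"] <- file.path(outdir, "fraction_matrix.tsv")
    readr::write_tsv(fraction_matrix(diff), files[["fraction_matrix"]],
                     progress = FALSE)
  }

  manifest <- write_manifest(config, input_files, files, outdir, status = 0L)
  list(status = 0L, outdir = outdir, files = files, qc = report,
       differential = diff, manifest = manifest)
}

write_manifest <- function(config, input_files, files, outdir, status) {
  cfg <- config
  cfg$simulate <- if (is.null(cfg$simulate)) {
    NULL
  } else {
    unclass(cfg$simulate)
  }
  manifest <- list(
    package = "kinomescore",
    version = as.character(utils::packageVersion("kinomescore")),
    status = status,
    seed = config$seed,
    config = cfg[setdiff(names(cfg), c("outdir"))],
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(input_files)), basename(input_files))),
    output_checksums = as.list(stats::setNames(
      unname(tools::md5sum(unname(files))), basename(unname(files))))
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}
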