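#' Configuration for synthetic kinome-array studies
#'
#' Bundles every knob of the synthetic-study generator. The defaults
#' emulate the wild-type versus knockout MEF design the analysis was
#' built for: a 1024-peptide array, two biological replicates with three
#' technical replicates each per condition, and knockout-side activation
#' (multiplier 4) of the mTOR, p70S6K, AMPK, Chk1/Chk2 and PAK signal
#' categories on top of a constitutively active background shared by
#' both conditions.
#'
#' The intensity model is multiplicative lognormal. For peptide `p` in
#' condition `c`, biological replicate `b`, technical replicate `t`:
#' \deqn{fg = \exp(\mu + e_p + \log m_{p,c} + B_{c,b,p} + T_{c,b,t,p})}
#' where `mu = baseline_log_mean`, `e_p ~ N(0, baseline_log_sd^2)` is a
#' fixed per-peptide propensity, `m` is the activity multiplier (1 for
#' inactive peptides), `B ~ N(0, sigma_bio^2)` is a per-spot biological
#' component shared by all technical replicates of one lysate, and
#' `T ~ N(0, sigma_tech^2)` is per-spot technical noise. Background is
#' drawn i.i.d. per spot from
#' `Lognormal(background_log_mean, background_log_sd)`. Because `B` is
#' shared within a lysate, technical replicates are more concordant than
#' biological replicates whenever `sigma_tech <= sigma_bio`.
#'
#' @param n_peptides Number of peptide substrates (default 1024).
#' @param category_spec Named integer vector: category label ->
#'   number of member peptides. Memberships are disjoint; their sum
#'   must not exceed `n_peptides`.
#' @param conditions Two condition labels (reference first).
#' @param n_bio,n_tech Biological and technical replicates per
#'   condition; the design has `R = n_bio * n_tech` reactions.
#' @param baseline_log_mean,baseline_log_sd Log-scale location of
#'   inactive foreground and SD of the per-peptide propensity `e_p`.
#' @param background_log_mean,background_log_sd Lognormal parameters of
#'   the per-spot local background.
#' @param activity_multipliers Tibble with columns `condition`,
#'   `category`, `multiplier` (> 0); a multiplier > 1 plants activation
#'   of that category in that condition.
#' @param constitutive_multiplier Foreground multiplier of
#'   constitutively active peptides (active in both conditions).
#' @param frac_constitutive Fraction of peptides outside any planted
#'   category that are constitutively active.
#' @param sigma_bio,sigma_tech Log-scale SDs of the biological and
#'   technical noise components; the default keeps
#'   `sigma_tech <= sigma_bio`.
#' @param frac_bad_spot Probability a spot is flagged `bad_spot`
#'   (default 0: clean arrays).
#' @param seed Integer seed; identical configurations give identical
#'   studies, including file serializations.
#' @return A validated `generation_config` object (a named list).
#' @seealso [simulate_study()], [make_layout()]
#' @export
generation_config <- function(n_peptides = 1024,
                              category_spec = default_category_spec(),
                              conditions = c("WT", "KO"),
                              n_bio = 2,
                              n_tech = 3,
                              baseline_log_mean = log(50),
                              baseline_log_sd = 0.25,
                              background_log_mean = log(50),
                              background_log_sd = 0.25,
                              activity_multipliers = default_activity_multipliers(),
                              constitutive_multiplier = 4,
                              frac_constitutive = 0.25,
                              sigma_bio = 0.15,
                              sigma_tech = 0.08,
                              frac_bad_spot = 0,
                              seed = 1L) {
  check_number(n_peptides, "n_peptides", min = 1, integer = TRUE)
  check_number(n_bio, "n_bio", min = 1, integer = TRUE)
  check_number(n_tech, "n_tech", min = 1, integer = TRUE)
  check_number(baseline_log_sd, "baseline_log_sd", min = 0)
  check_number(background_log_sd, "background_log_sd", min = 0)
  check_number(constitutive_multiplier, "constitutive_multiplier", min = 1e-12)
  check_number(frac_constitutive, "frac_constitutive", min = 0, max = 1)
  check_number(sigma_bio, "sigma_bio", min = 0)
  check_number(sigma_tech, "sigma_tech", min = 0)
  check_number(frac_bad_spot, "frac_bad_spot", min = 0, max = 1)
  check_number(seed, "seed", integer = TRUE)
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    kn_abort("`conditions` must be two distinct labels.")
  }
  category_spec <- validate_category_spec(category_spec, n_peptides)
  activity_multipliers <- validate_multipliers(activity_multipliers,
                                               names(category_spec),
                                               conditions)
  structure(
    list(
      n_peptides = as.integer(n_peptides),
      category_spec = category_spec,
      conditions = as.character(conditions),
      n_bio = as.integer(n_bio),
      n_tech = as.integer(n_tech),
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      background_log_mean = background_log_mean,
      background_log_sd = background_log_sd,
      activity_multipliers = activity_multipliers,
      constitutive_multiplier = constitutive_multiplier,
      frac_constitutive = frac_constitutive,
      sigma_bio = sigma_bio,
      sigma_tech = sigma_tech,
      frac_bad_spot = frac_bad_spot,
      seed = as.integer(seed)
    ),
    class = "generation_config"
  )
}

validate_category_spec <- function(category_spec, n_peptides) {
  if (length(category_spec) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (is.null(names(category_spec)) || any(!nzchar(names(category_spec))) ||
      anyDuplicated(names(category_spec))) {
    kn_abort("`category_spec` must have unique non-empty names.")
  }
  sizes <- as.integer(category_spec)
  if (any(is.na(sizes)) || any(sizes < 1L)) {
    kn_abort("`category_spec` sizes must be positive integers.")
  }
  if (sum(sizes) > n_peptides) {
    kn_abort(sprintf(
      "Categories oversubscribed: %d member peptides requested but n_peptides = %d.",
      sum(sizes), n_peptides
    ))
  }
  stats::setNames(sizes, names(category_spec))
}

validate_multipliers <- function(mult, categories, conditions) {
  if (is.null(mult) || (is.data.frame(mult) && nrow(mult) == 0L)) {
    return(tibble::tibble(condition = character(0), category = character(0),
                          multiplier = numeric(0)))
  }
  check_columns(mult, c("condition", "category", "multiplier"),
                "`activity_multipliers`")
  mult <- tibble::as_tibble(mult)
  if (any(!is.finite(mult$multiplier)) || any(mult$multiplier <= 0)) {
    kn_abort("Activity multipliers must be positive.")
  }
  if (any(!mult$condition %in% conditions)) {
    kn_abort("Activity multiplier refers to an unknown condition.")
  }
  unknown <- setdiff(mult$category, categories)
  if (length(unknown) > 0L) {
    kn_abort(sprintf("Activity multiplier refers to unknown category `%s`.",
                     unknown[[1L]]))
  }
  mult
}

#' @rdname generation_config
#' @export
default_category_spec <- function() {
  stats::setNames(
    rep(20L, 12L),
    c("mTOR", "p70S6K", "AMPK", "Chk1/Chk2", "PAK",
      "PKA", "PKC", "CK2", "GSK3", "CDK", "Src", "CaMK2")
  )
}

#' @rdname generation_config
#' @export
default_activity_multipliers <- function() {
  tibble::tibble(
    condition = "KO",
    category = c("mTOR", "p70S6K", "AMPK", "Chk1/Chk2", "PAK"),
    multiplier = 4
  )
}

#' Generate a synthetic array layout
#'
#' Builds an `n_peptides` layout on 16 x 16 blocks (row-major fill) and
#' assigns disjoint category memberships by a seeded random draw, so the
#' same configuration always produces a byte-identical layout file.
#' Peptides not claimed by any category remain unannotated.
#'
#' @param config A [generation_config()].
#' @return A validated layout tibble.
#' @export
make_layout <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  n <- config$n_peptides
  idx <- seq_len(n) - 1L
  layout <- tibble::tibble(
    peptide_id = sprintf("pep_%04d", seq_len(n)),
    block = idx %/% 256L,
    row = (idx %% 256L) %/% 16L,
    col = idx %% 16L,
    substrate_seq = NA_character_,
    categories = rep(list(character(0)), n)
  )
  spec <- config$category_spec
  if (length(spec) > 0L) {
    members <- withr::with_seed(config$seed, {
      picked <- sample.int(n, sum(spec))
      split(picked, rep(names(spec), spec))
    })
    for (cat in names(members)) {
      layout$categories[members[[cat]]] <-
        lapply(layout$categories[members[[cat]]], c, cat)
    }
  }
  validate_layout(layout)
}

#' Simulate a complete two-condition kinome-array study
#'
#' Draws a full study under the lognormal activity model documented in
#' [generation_config()]: an array layout, one quantification table per
#' reaction (`n_bio * n_tech` reactions per condition), and the ground
#' truth of which peptides and categories were planted as active. Fully
#' reproducible: the configuration seed drives the layout and a fixed
#' offset of it (`seed + 1`) drives the intensity draws, so partial
#' reruns agree with full runs.
#'
#' @param config A [generation_config()].
#' @return An object of class `kinome_study`: a list with elements
#'   `layout` (tibble), `quantifications` (one long tibble covering all
#'   reactions, keyed by `condition`, `bio_rep`, `tech_rep`), and
#'   `truth`, itself a list with `active` (tibble `condition`,
#'   `peptide_id`: peptides whose expected foreground exceeds baseline),
#'   `planted` (tibble `condition`, `category`: categories with
#'   multiplier > 1) and `constitutive` (character vector of peptide ids
#'   active in both conditions).
#' @examples
#' cfg <- generation_config(n_peptides = 64,
#'                          category_spec = c(A = 8, B = 8),
#'                          activity_multipliers =
#'                            tibble::tibble(condition = "KO",
#'                                           category = "A",
#'                                           multiplier = 4),
#'                          seed = 7)
#' study <- simulate_study(cfg)
#' dplyr::count(study$quantifications, condition, bio_rep, tech_rep)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  layout <- make_layout(config)
  n <- config$n_peptides
  cats <- layout_categories(layout)

  planted <- dplyr::filter(config$activity_multipliers, .data$multiplier > 1)
  planted_ids <- unique(
    cats$peptide_id[cats$category %in% unique(planted$category)]
  )

  draws <- withr::with_seed(config$seed + 1L, {
    eligible <- setdiff(layout$peptide_id, planted_ids)
    n_const <- round(config$frac_constitutive * length(eligible))
    constitutive <- sort(sample(eligible, n_const))
    e_p <- rnorm(n, 0, config$baseline_log_sd)
    quants <- vector("list", 2L * config$n_bio * config$n_tech)
    k <- 0L
    for (cond in config$conditions) {
      cond_planted <- dplyr::filter(planted, .data$condition == cond)
      log_mult <- rep(0, n)
      if (nrow(cond_planted) > 0L) {
        hit <- dplyr::inner_join(cats, cond_planted, by = "category")
        i <- match(hit$peptide_id, layout$peptide_id)
        log_mult[i] <- pmax(log_mult[i], log(hit$multiplier))
      }
      i_const <- match(constitutive, layout$peptide_id)
      log_mult[i_const] <- pmax(log_mult[i_const],
                                log(config$constitutive_multiplier))
      mu <- config$baseline_log_mean + e_p + log_mult
      for (b in seq_len(config$n_bio)) {
        bio_noise <- rnorm(n, 0, config$sigma_bio)
        for (t in seq_len(config$n_tech)) {
          tech_noise <- rnorm(n, 0, config$sigma_tech)
          fg <- exp(mu + bio_noise + tech_noise)
          bg <- rlnorm(n, config$background_log_mean, config$background_log_sd)
          flag <- ifelse(stats::runif(n) < config$frac_bad_spot,
                         "bad_spot", "ok")
          k <- k + 1L
          quants[[k]] <- tibble::tibble(
            condition = cond, bio_rep = b, tech_rep = t,
            peptide_id = layout$peptide_id,
            foreground_density = fg,
            background_density = bg,
            flag = flag
          )
        }
      }
    }
    list(quants = dplyr::bind_rows(quants), constitutive = constitutive)
  })

  active <- dplyr::bind_rows(lapply(config$conditions, function(cond) {
    cond_planted <- planted$category[planted$condition == cond]
    ids <- union(
      draws$constitutive,
      cats$peptide_id[cats$category %in% cond_planted]
    )
    tibble::tibble(condition = cond,
                   peptide_id = sort(ids))
  }))

  structure(
    list(
      layout = layout,
      quantifications = draws$quants,
      truth = list(
        active = active,
        planted = dplyr::select(planted, "condition", "category"),
        constitutive = draws$constitutive
      ),
      config = config
    ),
    class = "kinome_study"
  )
}

#' Write a simulated study to disk
#'
#' Serializes a [simulate_study()] result into the pipeline's file
#' dialects: `layout.tsv`, one quantification TSV per reaction named
#' `<condition>_b<k>_t<m>.tsv`, and `truth.json` with the planted ground
#' truth. Writes are deterministic (layout order, fixed filename
#' grammar), so identical configurations give byte-identical trees.
#'
#' @param study A `kinome_study`.
#' @param outdir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "kinome_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(outdir, "layout.tsv")
  write_layout(study$layout, files)
  reactions <- dplyr::group_split(
    study$quantifications,
    .data$condition, .data$bio_rep, .data$tech_rep
  )
  for (q in reactions) {
    path <- file.path(outdir, reaction_filename(q$condition[[1L]],
                                                q$bio_rep[[1L]],
                                                q$tech_rep[[1L]]))
    write_quantification(q, path)
    files <- c(files, path)
  }
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(
      active = study$truth$active,
      planted = study$truth$planted,
      constitutive = study$truth$constitutive
    ),
    truth_path, dataframe = "columns", pretty = TRUE
  )
  invisible(c(files, truth_path))
}

#' @export
print.kinome_study <- function(x, ...) {
  n_rxn <- dplyr::n_distinct(reaction_key(x$quantifications$condition,
                                          x$quantifications$bio_rep,
                                          x$quantifications$tech_rep))
  cat(sprintf(
    "<kinome_study> %d peptides, conditions %s, %d reactions, %d planted categories\n",
    nrow(x$layout), paste(x$config$conditions, collapse = "/"),
    n_rxn, nrow(x$truth$planted)
  ))
  invisible(x)
}
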