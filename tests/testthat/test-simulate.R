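test_that("identical configurations give identical studies and files", {
  cfg <- small_config(seed = 5L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_equal(s1$quantifications, s2$quantifications)
  expect_equal(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(s2, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("a study lays out the full design with all-positive densities", {
  cfg <- small_config(seed = 2L)
  study <- simulate_study(cfg)
  rxn <- dplyr::count(study$quantifications, condition, bio_rep, tech_rep)
  expect_equal(nrow(rxn), 12L) # 2 conditions x 2 bio x 3 tech
  expect_true(all(rxn$n == 128L))
  expect_true(all(study$quantifications$foreground_density > 0))
  expect_true(all(study$quantifications$background_density > 0))
})

test_that("unit multipliers mean no planted categories", {
  cfg <- small_config(seed = 4L, multipliers = NULL)
  study <- simulate_study(cfg)
  expect_equal(nrow(study$truth$planted), 0L)
  # constitutive actives are shared by both conditions
  by_cond <- split(study$truth$active$peptide_id,
                   study$truth$active$condition)
  expect_setequal(by_cond$WT, by_cond$KO)
})

test_that("every peptide of a planted category is active in that condition", {
  study <- simulate_study(small_config(seed = 6L))
  cats <- layout_categories(study$layout)
  pak <- cats$peptide_id[cats$category == "PAK"]
  ko_active <- study$truth$active$peptide_id[
    study$truth$active$condition == "KO"
  ]
  expect_true(all(pak %in% ko_active))
  wt_active <- study$truth$active$peptide_id[
    study$truth$active$condition == "WT"
  ]
  expect_false(any(pak %in% wt_active)) # planted set excluded from baseline
})

test_that("category saturation and oversubscription behave at the edges", {
  cfg <- generation_config(n_peptides = 10L, category_spec = c(ALL = 10L),
                           activity_multipliers = NULL, seed = 1L)
  layout <- make_layout(cfg)
  expect_true(all(lengths(layout$categories) == 1L))

  expect_error(
    generation_config(n_peptides = 10L, category_spec = c(A = 6L, B = 5L),
                      activity_multipliers = NULL),
    "oversubscribed", ignore.case = TRUE
  )
})

test_that("with zero noise, replicates coincide and means recover the multiplier", {
  cfg <- generation_config(
    n_peptides = 10000L,
    category_spec = c(mTOR = 2000L),
    activity_multipliers = tibble::tibble(condition = "KO",
                                          category = "mTOR",
                                          multiplier = 4),
    frac_constitutive = 0,
    sigma_bio = 0, sigma_tech = 0,
    seed = 9L
  )
  study <- simulate_study(cfg)
  ko <- dplyr::filter(study$quantifications, condition == "KO")
  wide <- tidyr::pivot_wider(
    ko, id_cols = "peptide_id",
    names_from = c("bio_rep", "tech_rep"),
    values_from = "foreground_density"
  )
  mat <- as.matrix(wide[, -1])
  expect_true(all(mat == mat[, 1])) # identical up to background draws

  cats <- layout_categories(study$layout)
  planted <- wide$peptide_id %in% cats$peptide_id
  m_planted <- mean(mat[planted, 1])
  m_base <- mean(mat[!planted, 1])
  ratio <- m_planted / m_base
  # lognormal group means: 3-standard-error band via the delta method
  cv2 <- exp(cfg$baseline_log_sd^2) - 1
  se <- ratio * sqrt(cv2 / sum(planted) + cv2 / sum(!planted))
  expect_lt(abs(ratio - 4), 3 * se)

  # law of large numbers on the log scale
  lr <- mean(log(mat[planted, 1])) - mean(log(mat[!planted, 1]))
  se_lr <- cfg$baseline_log_sd * sqrt(1 / sum(planted) + 1 / sum(!planted))
  expect_lt(abs(lr - log(4)), 3 * se_lr)
})

test_that("bad-spot planting marks roughly the requested fraction", {
  study <- simulate_study(small_config(seed = 11L, frac_bad_spot = 0.1))
  f <- mean(study$quantifications$flag == "bad_spot")
  expect_gt(f, 0.05)
  expect_lt(f, 0.15)
})
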