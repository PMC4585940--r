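profile_from_scores <- function(scores, condition, R = 6L) {
  tibble::tibble(
    condition = condition,
    peptide_id = names(scores),
    markov_score = as.integer(scores),
    n_called = as.integer(R),
    R = as.integer(R)
  )
}

test_that("comparing a profile with itself yields zero deltas and p = 1", {
  layout <- tiny_layout(8L, categories = c(rep(list("A"), 4),
                                           rep(list("B"), 4)))
  scores <- stats::setNames(c(6, 5, 0, 1, 6, 6, 0, 0), layout$peptide_id)
  pa <- profile_from_scores(scores, "WT")
  pb <- profile_from_scores(scores, "KO")
  d <- differential_categories(pa, pb, layout, tau = 4, n_perm = 200,
                               seed = 1)
  expect_equal(d$delta, c(0, 0))
  expect_equal(d$p_value, c(1, 1))
  expect_equal(d$q_value, c(1, 1))
})

test_that("Monte-Carlo p-values agree with complete enumeration", {
  layout <- tiny_layout(8L, categories = c(rep(list("A"), 4),
                                           rep(list("B"), 4)))
  cases <- list(
    list(a = c(6, 6, 6, 0, 0, 0, 6, 0), b = c(6, 6, 6, 6, 0, 6, 6, 0)),
    list(a = c(0, 0, 0, 0, 6, 6, 0, 0), b = c(6, 6, 0, 0, 6, 0, 0, 6)),
    list(a = c(6, 0, 6, 0, 6, 0, 6, 0), b = c(0, 6, 0, 6, 0, 6, 0, 6))
  )
  n_perm <- 4000L
  for (case in cases) {
    pa <- profile_from_scores(stats::setNames(case$a, layout$peptide_id), "WT")
    pb <- profile_from_scores(stats::setNames(case$b, layout$peptide_id), "KO")
    d <- differential_categories(pa, pb, layout, tau = 4, n_perm = n_perm,
                                 seed = 99)
    dvec <- (case$b >= 4) - (case$a >= 4)
    exact <- enumerate_p(dvec, d$delta)
    for (k in 1:2) {
      tol <- 3 * sqrt(exact[k] * (1 - exact[k]) / n_perm) + 2 / n_perm
      expect_lt(abs(d$p_value[k] - exact[k]), tol + 1e-12)
    }
  }
})

test_that("planted categories and only planted categories are recovered", {
  hits <- 0L
  n_seeds <- 3L
  for (s in seq_len(n_seeds)) {
    study <- simulate_study(small_config(seed = 200L + s))
    calls <- call_phosphostates(study$quantifications)
    prof <- markov_scores(calls, study$layout)
    d <- differential_categories(
      dplyr::filter(prof, condition == "WT"),
      dplyr::filter(prof, condition == "KO"),
      study$layout, tau = 4, n_perm = 1000, seed = s
    )
    reported <- d$category[d$q_value < 0.05 & d$delta > 0]
    if (setequal(reported, c("mTOR", "PAK"))) hits <- hits + 1L
    # planted categories always rank above non-planted by |delta|
    expect_gt(min(abs(d$delta[d$category %in% c("mTOR", "PAK")])),
              max(abs(d$delta[!d$category %in% c("mTOR", "PAK")])))
  }
  expect_equal(hits, n_seeds)
})

test_that("determinism, guard rails and metadata behave", {
  layout <- tiny_layout(8L, categories = c(rep(list("A"), 4),
                                           rep(list("B"), 4)))
  pa <- profile_from_scores(stats::setNames(c(6, 6, 0, 0, 0, 6, 0, 6),
                                            layout$peptide_id), "WT")
  pb <- profile_from_scores(stats::setNames(c(6, 6, 6, 6, 0, 0, 0, 6),
                                            layout$peptide_id), "KO")
  d1 <- differential_categories(pa, pb, layout, tau = 4, n_perm = 500,
                                seed = 7)
  d2 <- differential_categories(pa, pb, layout, tau = 4, n_perm = 500,
                                seed = 7)
  expect_equal(tibble::as_tibble(d1), tibble::as_tibble(d2))

  expect_warning(
    differential_categories(pa, pb, layout, tau = 4, n_perm = 50, seed = 1),
    "coarse"
  )
  other <- tiny_layout(6L, categories = rep(list("A"), 6))
  expect_error(differential_categories(pa, pb, other, tau = 4, seed = 1),
               "layout")
  # BH q-values are a monotone transform sitting at or above p
  expect_true(all(d1$q_value >= d1$p_value))
  g <- glance(d1)
  expect_equal(g$condition_a, "WT")
  expect_equal(g$condition_b, "KO")
  fm <- fraction_matrix(d1)
  expect_equal(names(fm), c("category", "WT", "KO"))
  expect_equal(fm$KO, d1$f_b)
})

test_that("permutation p-values are valid (never anti-conservative) under the null", {
  # the tie-inclusive add-one estimator is conservative by design; the
  # defensible calibration property is P(p <= alpha) <= alpha
  ps <- vapply(1:100, function(s) {
    cfg <- generation_config(
      n_peptides = 64L, category_spec = c(A = 32L, B = 32L),
      activity_multipliers = NULL, constitutive_multiplier = 2,
      frac_constitutive = 0.5, baseline_log_sd = 0.1,
      sigma_bio = 0.7, sigma_tech = 0.3, seed = 3000L + s
    )
    study <- simulate_study(cfg)
    calls <- call_phosphostates(study$quantifications)
    prof <- markov_scores(calls, study$layout)
    d <- suppressWarnings(differential_categories(
      dplyr::filter(prof, condition == "WT"),
      dplyr::filter(prof, condition == "KO"),
      study$layout, tau = 4, n_perm = 200, seed = s
    ))
    d$p_value[d$category == "A"]
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 100))
  }
})

test_that("peptides unusable in either profile leave the comparison", {
  layout <- tiny_layout(8L, categories = c(rep(list("A"), 4),
                                           rep(list("B"), 4)))
  pa <- profile_from_scores(stats::setNames(rep(0, 8), layout$peptide_id),
                            "WT")
  pb <- profile_from_scores(stats::setNames(rep(6, 8), layout$peptide_id),
                            "KO")
  pa$n_called[1:2] <- 2L # below R/2 in profile A
  pa$markov_score[1:2] <- 0L
  d <- differential_categories(pa, pb, layout, tau = 4, n_perm = 200,
                               seed = 3)
  expect_equal(d$n, c(2L, 4L))
})
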