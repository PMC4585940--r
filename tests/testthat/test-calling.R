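test_that("background correction floors at zero and matches a loop oracle", {
  q <- make_quant(c("p1", "p2"), fg = c(100, 10), bg = c(30, 25))
  cq <- correct_background(q)
  expect_equal(cq$corrected, c(70, 0))

  withr::local_seed(21)
  big <- make_quant(sprintf("p%04d", 1:1024),
                    fg = stats::runif(1024, 0, 500),
                    bg = stats::runif(1024, 0, 200),
                    flag = sample(c("ok", "bad_spot"), 1024, TRUE,
                                  prob = c(0.97, 0.03)))
  cq <- correct_background(big)
  expect_identical(cq$corrected,
                   naive_correct(big$foreground_density,
                                 big$background_density, big$flag))
})

test_that("EM recovers planted mixture parameters (seed-averaged)", {
  seps <- numeric(5)
  pis <- numeric(5)
  for (s in 1:5) {
    vals <- withr::with_seed(100 + s, {
      c(exp(rnorm(400, 2, 0.3)), exp(rnorm(100, 6, 0.3)))
    })
    fit <- fit_two_state(vals)
    expect_false(fit$degenerate)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
    seps[s] <- fit$mu1 - fit$mu0
    pis[s] <- fit$pi1
  }
  # log1p compresses the lower component slightly, so the target
  # separation is log1p-adjusted 4
  expect_lt(abs(mean(seps) - 4), 0.2)
  expect_lt(abs(mean(pis) - 0.2), 0.05)
})

test_that("degenerate and undersized inputs fall back or fail as documented", {
  fit0 <- fit_two_state(rep(0, 100))
  expect_true(fit0$degenerate)
  q <- make_quant(paste0("p", 1:100), fg = rep(5, 100), bg = rep(10, 100))
  calls <- call_states(correct_background(q), fit0)
  expect_true(all(calls$state == "background"))
  expect_true(all(calls$posterior == 0))

  expect_error(fit_two_state(rep(c(0, 10), 5)), "at least 20")
})

test_that("posteriors agree with a hand-coded density calculator", {
  vals <- withr::with_seed(7, c(exp(rnorm(300, 1.5, 0.4)),
                                exp(rnorm(120, 5.5, 0.4))))
  fit <- fit_two_state(vals)
  probe <- c(0, 0.5, 2, 7, 50, 400, 2000)
  expect_equal(posterior_phospho(fit, probe), hand_posterior(fit, probe),
               tolerance = 1e-12)
  # zero and near-zero corrected values are confidently background
  expect_lt(posterior_phospho(fit, 0), 0.01)
  expect_lt(posterior_phospho(fit, 0.5), 0.01)
})

test_that("a posterior exactly at threshold calls the phosphorylated state", {
  model <- structure(
    list(mu0 = 1, mu1 = 3, sigma0 = 0.5, sigma1 = 0.5, pi1 = 0.5,
         loglik = NA_real_, loglik_trace = numeric(0), iterations = 0L,
         converged = TRUE, degenerate = FALSE, n = 0L),
    class = "two_state_model"
  )
  midpoint <- expm1(2) # equidistant from both components
  q <- make_quant("p1", fg = midpoint, bg = 0)
  calls <- call_states(correct_background(q), model)
  expect_equal(calls$posterior, 0.5)
  expect_equal(calls$state, "phosphorylated")
  expect_error(call_states(correct_background(q), model, threshold = 1.5),
               "0, 1")
})

test_that("with equal variances the posterior is monotone in corrected", {
  vals <- withr::with_seed(9, c(exp(rnorm(250, 2, 0.5)),
                                exp(rnorm(250, 5, 0.5))))
  fit <- fit_two_state(vals)
  eq <- fit
  eq$sigma0 <- eq$sigma1 <- (fit$sigma0 + fit$sigma1) / 2
  grid <- sort(withr::with_seed(10, stats::runif(200, 0, 1000)))
  post <- posterior_phospho(eq, grid)
  expect_true(all(diff(post) >= -1e-12))
})

test_that("calls are stable under a common intensity rescaling", {
  study <- simulate_study(small_config(seed = 14L))
  one <- dplyr::filter(study$quantifications, condition == "KO",
                       bio_rep == 1, tech_rep == 1)
  base <- call_states(correct_background(one),
                      fit_two_state(correct_background(one)$corrected))
  scaled_q <- dplyr::mutate(one,
                            foreground_density = foreground_density * 10,
                            background_density = background_density * 10)
  scaled <- call_states(correct_background(scaled_q),
                        fit_two_state(correct_background(scaled_q)$corrected))
  expect_equal(
    base$peptide_id[base$state == "phosphorylated"],
    scaled$peptide_id[scaled$state == "phosphorylated"]
  )
})

test_that("the per-study driver fits each reaction independently", {
  study <- simulate_study(small_config(seed = 15L, frac_bad_spot = 0.02))
  calls <- call_phosphostates(study$quantifications)
  expect_equal(nrow(calls), nrow(study$quantifications))
  models <- attr(calls, "models")
  expect_length(models, 12L)
  for (m in models) {
    expect_true(all(diff(m$loglik_trace) >= -1e-6 * abs(m$loglik)))
  }
  # bad spots and only bad spots yield no_call
  key <- function(df) paste(df$condition, df$bio_rep, df$tech_rep,
                            df$peptide_id)
  flags <- study$quantifications$flag[
    match(key(calls), key(study$quantifications))
  ]
  expect_identical(calls$state == "no_call", flags == "bad_spot")
})

test_that("under a null study the call rate tracks the constitutive fraction", {
  cfg <- small_config(seed = 16L, multipliers = NULL)
  study <- simulate_study(cfg)
  calls <- call_phosphostates(study$quantifications)
  truth_f <- length(study$truth$constitutive) / cfg$n_peptides
  per_rxn <- calls |>
    dplyr::group_by(condition, bio_rep, tech_rep) |>
    dplyr::summarise(f = mean(state == "phosphorylated"), .groups = "drop")
  band <- 3 * sqrt(truth_f * (1 - truth_f) / cfg$n_peptides)
  expect_true(all(abs(per_rxn$f - truth_f) <= band))
})

test_that("the z-score fallback calls only clear outliers", {
  study <- simulate_study(small_config(seed = 17L))
  calls <- call_phosphostates(study$quantifications, method = "zscore",
                              zscore_k = 3)
  expect_true(all(calls$state %in% c("phosphorylated", "background")))
  expect_true(all(calls$posterior %in% c(0, 1)))
  # planted KO categories should still light up
  cats <- layout_categories(study$layout)
  ko <- dplyr::filter(calls, condition == "KO",
                      peptide_id %in% cats$peptide_id[cats$category == "PAK"])
  expect_gt(mean(ko$state == "phosphorylated"), 0.6)
})

test_that("EM agrees with an independent mixture implementation", {
  withr::local_package("mclust")
  vals <- withr::with_seed(23, c(exp(rnorm(350, 2, 0.35)),
                                 exp(rnorm(150, 5.5, 0.35))))
  fit <- fit_two_state(vals)
  ref <- mclust::Mclust(log1p(vals), G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_equal(sort(c(fit$mu0, fit$mu1)),
               sort(unname(ref$parameters$mean)), tolerance = 0.05)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-3)
})
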