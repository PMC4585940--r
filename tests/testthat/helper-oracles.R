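# Independent brute-force oracles. Each is deliberately naive (loops,
# two-pass formulas, exhaustive enumeration) and shares no code with the
# implementation it checks.

# regex-free character-walk parser for <condition>_b<k>_t<m> filenames
walk_parse_reaction <- function(name) {
  chars <- strsplit(name, "", fixed = TRUE)[[1L]]
  i <- length(chars)
  digits <- c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9")
  take_int <- function(i) {
    ds <- character(0)
    while (i >= 1L && chars[i] %in% digits) {
      ds <- c(chars[i], ds)
      i <- i - 1L
    }
    if (length(ds) == 0L) stop("no digits")
    list(value = as.integer(paste(ds, collapse = "")), i = i)
  }
  t_part <- take_int(i)
  if (t_part$i < 2L || chars[t_part$i] != "t" || chars[t_part$i - 1L] != "_") {
    stop("bad _t segment")
  }
  b_part <- take_int(t_part$i - 2L)
  if (b_part$i < 2L || chars[b_part$i] != "b" || chars[b_part$i - 1L] != "_") {
    stop("bad _b segment")
  }
  cond <- paste(chars[seq_len(b_part$i - 2L)], collapse = "")
  if (!nzchar(cond)) stop("empty condition")
  list(condition = cond, bio_rep = b_part$value, tech_rep = t_part$value)
}

# two-pass covariance Pearson correlation
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- 0
  sxx <- 0
  syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# elementwise loop background correction
naive_correct <- function(fg, bg, flag) {
  out <- numeric(length(fg))
  for (i in seq_along(fg)) {
    if (flag[i] == "bad_spot") {
      out[i] <- NA_real_
    } else {
      d <- fg[i] - bg[i]
      out[i] <- if (d > 0) d else 0
    }
  }
  out
}

# double-loop Markov score counter
naive_markov <- function(calls) {
  peptides <- unique(calls$peptide_id)
  rxns <- unique(paste(calls$bio_rep, calls$tech_rep))
  score <- integer(length(peptides))
  called <- integer(length(peptides))
  for (i in seq_along(peptides)) {
    for (j in seq_along(rxns)) {
      row <- calls[calls$peptide_id == peptides[i] &
                     paste(calls$bio_rep, calls$tech_rep) == rxns[j], ]
      if (row$state == "phosphorylated") score[i] <- score[i] + 1L
      if (row$state != "no_call") called[i] <- called[i] + 1L
    }
  }
  data.frame(peptide_id = peptides, markov_score = score, n_called = called)
}

# filter-and-count category fractions
naive_fractions <- function(profile, layout, tau) {
  res <- list()
  for (cat in sort(unique(unlist(layout$categories)))) {
    members <- layout$peptide_id[vapply(layout$categories,
                                        function(v) cat %in% v, logical(1))]
    rows <- profile[profile$peptide_id %in% members &
                      profile$n_called >= profile$R / 2, ]
    if (nrow(rows) == 0) next
    res[[cat]] <- data.frame(
      category = cat, n = nrow(rows),
      fraction = sum(rows$markov_score >= tau) / nrow(rows)
    )
  }
  do.call(rbind, res)
}

# hand-coded two-component posterior (no dnorm)
hand_posterior <- function(model, corrected) {
  y <- log1p(corrected)
  dens <- function(v, mu, s) exp(-(v - mu)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  f0 <- (1 - model$pi1) * dens(y, model$mu0, model$sigma0)
  f1 <- model$pi1 * dens(y, model$mu1, model$sigma1)
  ifelse(corrected == 0, 0, f1 / (f0 + f1))
}

# exact permutation p-values by complete enumeration of category-A
# member subsets (two categories of size 4 over 8 peptides)
enumerate_p <- function(d, obs_delta) {
  combos <- combn(8L, 4L)
  stats_a <- numeric(ncol(combos))
  stats_b <- numeric(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    a <- combos[, j]
    stats_a[j] <- abs(mean(d[a]))
    stats_b[j] <- abs(mean(d[-a]))
  }
  c(
    A = mean(stats_a >= abs(obs_delta[1L])),
    B = mean(stats_b >= abs(obs_delta[2L]))
  )
}
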