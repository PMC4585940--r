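#' Fit the two-state phosphorylation model for one reaction
#'
#' Realizes the per-reaction binary latent-state ("is this peptide
#' significantly more phosphorylated than background?") classification
#' as a two-component Gaussian mixture on `log1p` background-corrected
#' density, fitted by expectation-maximization. The fit is fully
#' deterministic: components are initialized at the 25th and 75th
#' percentiles of the data with equal weights and a pooled standard
#' deviation, and iteration stops when the relative log-likelihood
#' change drops below `tol` (default 1e-8) or after `max_iter`
#' iterations. Components are relabelled after fitting so that
#' `mu0 < mu1` (component 1 is the phosphorylated state).
#'
#' Background subtraction floors at zero, so spots whose foreground does
#' not exceed their local background pile up in a point mass at
#' `corrected = 0`. A Gaussian component cannot represent a point mass:
#' left in the data it swallows one component (the fitted "background"
#' state collapses onto the atom and everything positive gets called).
#' Exact zeros are therefore background by definition — their posterior
#' is 0 without reference to the model — and the mixture is fitted to
#' the strictly positive corrected values only, where it separates the
#' background noise halo from genuinely phosphorylated spots. As a
#' numerical safeguard component standard deviations are floored at
#' `sigma_floor` (log-scale units). The log-likelihood is non-decreasing
#' across iterations, which the fitter asserts (to within
#' floating-point tolerance; the floor can bind only degenerately).
#'
#' @param corrected Numeric vector of background-corrected densities
#'   (raw scale, >= 0). `NA` entries (flagged bad spots) are dropped.
#'   At least 20 usable values are required; fewer than 20 *positive*
#'   values yields the degenerate all-background model.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param sigma_floor Lower bound on component SDs (log scale).
#' @return A `two_state_model`: list with `mu0`, `mu1`, `sigma0`,
#'   `sigma1`, `pi1` (mixing weight of the phosphorylated component),
#'   `loglik`, `loglik_trace`, `iterations`, `converged`, `degenerate`,
#'   `n`. A degenerate input (all values identical) yields a fallback
#'   single-state model in which every peptide is background.
#' @seealso [call_states()] to turn a fitted model into calls,
#'   [posterior_phospho()] for the posterior itself.
#' @export
fit_two_state <- function(corrected, max_iter = 500L, tol = 1e-8,
                          sigma_floor = 0.1) {
  x <- corrected[!is.na(corrected)]
  if (length(x) < 20L) {
    kn_abort(sprintf(
      "Two-state fit needs at least 20 usable peptides, got %d.", length(x)
    ))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    kn_abort("Corrected densities must be finite and non-negative.")
  }
  # zeros are censored background mass, not data for the mixture
  y <- log1p(x[x > 0])
  n <- length(y)
  if (n < 20L || diff(range(y)) == 0) {
    return(degenerate_model(if (n > 0L) mean(y) else 0, n))
  }

  mu <- unname(quantile(y, c(0.25, 0.75), names = FALSE, type = 7))
  if (mu[[1L]] == mu[[2L]]) {
    # quartiles can coincide on a zero-heavy atom; fall back to the range
    mu <- range(y)
  }
  s <- max(sd(y), sigma_floor)
  sigma <- c(s, s)
  pi1 <- 0.5

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    la <- dnorm(y, mu[[1L]], sigma[[1L]], log = TRUE) + log1p(-pi1)
    lb <- dnorm(y, mu[[2L]], sigma[[2L]], log = TRUE) + log(pi1)
    m <- pmax(la, lb)
    ll <- sum(m + log(exp(la - m) + exp(lb - m)))
    if (is.finite(ll_prev) && ll < ll_prev - 1e-6 * abs(ll_prev) - 1e-9) {
      kn_abort("EM log-likelihood decreased; two-state fit is inconsistent.")
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      resp <- 1 / (1 + exp(la - lb))
      break
    }
    ll_prev <- ll
    r1 <- 1 / (1 + exp(la - lb))
    resp <- r1
    w1 <- sum(r1)
    w0 <- n - w1
    if (w1 < 1e-8 || w0 < 1e-8) {
      # one component vanished: the data are effectively single-state
      return(degenerate_model(mean(y), n, sd_y = max(sd(y), sigma_floor),
                              trace = trace, iterations = iter))
    }
    mu <- c(sum((1 - r1) * y) / w0, sum(r1 * y) / w1)
    sigma <- c(
      max(sqrt(sum((1 - r1) * (y - mu[[1L]])^2) / w0), sigma_floor),
      max(sqrt(sum(r1 * (y - mu[[2L]])^2) / w1), sigma_floor)
    )
    pi1 <- w1 / n
  }

  if (mu[[1L]] > mu[[2L]]) {
    mu <- rev(mu)
    sigma <- rev(sigma)
    pi1 <- 1 - pi1
  }
  structure(
    list(
      mu0 = mu[[1L]], mu1 = mu[[2L]],
      sigma0 = sigma[[1L]], sigma1 = sigma[[2L]],
      pi1 = pi1,
      loglik = trace[[length(trace)]],
      loglik_trace = trace,
      iterations = iter,
      converged = converged,
      degenerate = FALSE,
      n = n
    ),
    class = "two_state_model"
  )
}

degenerate_model <- function(mu, n, sd_y = 0, trace = numeric(0),
                             iterations = 0L) {
  structure(
    list(
      mu0 = mu, mu1 = mu, sigma0 = sd_y, sigma1 = sd_y, pi1 = 0,
      loglik = if (length(trace)) trace[[length(trace)]] else NA_real_,
      loglik_trace = trace,
      iterations = iterations,
      converged = TRUE,
      degenerate = TRUE,
      n = n
    ),
    class = "two_state_model"
  )
}

#' Posterior probability of the phosphorylated state
#'
#' Evaluates `P(phosphorylated | log1p(corrected))` under a fitted
#' two-state model. Corrected densities of exactly 0 (foreground at or
#' below local background) are background by definition and get
#' posterior 0. For a degenerate (single-state) model the posterior is 0
#' everywhere: nothing is significantly above background. `NA` inputs
#' (bad spots) give `NA`.
#'
#' @param model A `two_state_model`.
#' @param corrected Numeric vector of background-corrected densities.
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
posterior_phospho <- function(model, corrected) {
  stopifnot(inherits(model, "two_state_model"))
  out <- rep(NA_real_, length(corrected))
  out[!is.na(corrected) & corrected == 0] <- 0
  ok <- !is.na(corrected) & corrected > 0
  if (model$degenerate || model$pi1 <= 0) {
    out[ok] <- 0
    return(out)
  }
  y <- log1p(corrected[ok])
  la <- dnorm(y, model$mu0, model$sigma0, log = TRUE) + log1p(-model$pi1)
  lb <- dnorm(y, model$mu1, model$sigma1, log = TRUE) + log(model$pi1)
  out[ok] <- 1 / (1 + exp(la - lb))
  out
}

#' @export
print.two_state_model <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<two_state_model> degenerate (single state), n = %d\n", x$n))
  } else {
    cat(sprintf(
      "<two_state_model> n = %d, mu0 = %.3f (sd %.3f), mu1 = %.3f (sd %.3f), pi1 = %.3f\n  %d iterations, %sconverged, loglik %.2f\n",
      x$n, x$mu0, x$sigma0, x$mu1, x$sigma1, x$pi1,
      x$iterations, if (x$converged) "" else "NOT ", x$loglik
    ))
  }
  invisible(x)
}

#' @method tidy two_state_model
#' @export
tidy.two_state_model <- function(x, ...) {
  tibble::tibble(
    component = c("background", "phosphorylated"),
    mean = c(x$mu0, x$mu1),
    sd = c(x$sigma0, x$sigma1),
    weight = c(1 - x$pi1, x$pi1)
  )
}

#' @method glance two_state_model
#' @export
glance.two_state_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    loglik = x$loglik,
    iterations = x$iterations,
    converged = x$converged,
    degenerate = x$degenerate,
    separation = x$mu1 - x$mu0
  )
}
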