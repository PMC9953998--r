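# Independent oracles used across the suite.  All are deliberately naive:
# direct transcriptions of the defining formulas, never calling the code
# paths they check.

# Partial log-likelihood for a binary covariate (Efron or Breslow ties),
# computed straight from the risk-set definition.
oracle_partial_loglik <- function(time, event, x, beta, ties = "efron") {
  vapply(beta, function(b) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      ev <- which(event == 1 & time == t)
      risk <- which(time >= t)
      d <- length(ev)
      d1 <- sum(x[ev])
      r1 <- sum(x[risk])
      r0 <- length(risk) - r1
      ll <- ll + d1 * b
      for (j in seq_len(d) - 1) {
        f <- if (ties == "efron") j / d else 0
        ll <- ll - log((r1 - f * d1) * exp(b) + (r0 - f * (d - d1)))
      }
    }
    ll
  }, numeric(1))
}

# Numerical second derivative of a scalar function.
oracle_d2 <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# Firth-penalized objective: l(beta) + log(-l''(beta)) / 2, with the second
# derivative taken numerically from the oracle log-likelihood.  The inner
# step is 1e-3: small enough for the smooth partial likelihood, large
# enough that the objective itself is accurate to ~1e-8, so an outer
# numerical derivative with h ~ 1e-2 stays meaningful.
oracle_firth_loglik <- function(time, event, x, beta, ties = "efron") {
  vapply(beta, function(b) {
    f <- function(bb) oracle_partial_loglik(time, event, x, bb, ties)
    d2 <- oracle_d2(f, b, h = 1e-3)
    # far in the tails the numerical information underflows into noise;
    # treat non-positive values as zero information
    if (!is.finite(d2) || d2 >= 0) return(-Inf)
    f(b) + 0.5 * log(-d2)
  }, numeric(1))
}

# Two-stage grid argmax: coarse pass, then a fine pass around the winner.
oracle_grid_argmax <- function(f, lower = -10, upper = 10, fine = 1e-4) {
  coarse <- seq(lower, upper, by = 0.01)
  b0 <- coarse[which.max(f(coarse))]
  grid <- seq(max(lower, b0 - 0.02), min(upper, b0 + 0.02), by = fine)
  grid[which.max(f(grid))]
}

# Upper-tail chi-squared(1) probability through the complementary error
# function: P(X > x) = erfc(sqrt(x / 2)).
oracle_chi2_upper <- function(x) pracma::erfc(sqrt(x / 2))

# Exhaustive cut-off search: every admissible split, each fitted by the
# grid oracle on the partial likelihood, scored by the Wald chi-squared
# with variance from the numerical second derivative.
oracle_best_cutoff <- function(time, event, marker, min_group_size = 1) {
  cuts <- sort(unique(marker))
  best <- NULL
  for (cc in cuts) {
    x <- as.integer(marker > cc)
    if (sum(x) < min_group_size || sum(1 - x) < min_group_size) next
    firth <- sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0
    f <- if (firth) function(b) oracle_firth_loglik(time, event, x, b)
         else function(b) oracle_partial_loglik(time, event, x, b)
    bhat <- oracle_grid_argmax(f, -8, 8, fine = 1e-3)
    if (!firth && abs(bhat) > 7.5) {
      # monotone likelihood without a zero-event group (an event whose
      # risk set is single-group): the MLE diverges, Firth applies
      firth <- TRUE
      f <- function(b) oracle_firth_loglik(time, event, x, b)
      bhat <- oracle_grid_argmax(f, -8, 8, fine = 1e-3)
    }
    v <- -1 / oracle_d2(f, bhat, h = if (firth) 1e-2 else 1e-4)
    chi2 <- bhat^2 / v
    if (is.null(best) || chi2 > best$chi2 + 1e-9)
      best <- list(cutoff = cc, chi2 = chi2, beta = bhat)
  }
  best
}

# Small random survival dataset generator for property tests.
random_small_data <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:12, 1)
  time <- round(rexp(n, 0.3), 3) + 0.001
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[sample(n, 1)] <- 1L
  marker <- rnorm(n)
  survival_data(time, event, marker)
}
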