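test_that("partial-likelihood fit matches a brute-force grid oracle", {
  # the no-ties example has Breslow = Efron, so the plain oracle applies;
  # the alternating indicator keeps the likelihood non-monotone
  d <- survival_data(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 1, 3, 2))
  g <- dichotomize(d, 2.5)
  fit <- fit_cox_binary(d, g)
  bhat <- oracle_grid_argmax(function(b)
    oracle_partial_loglik(d$time, d$event, g$indicator, b))
  expect_false(fit$used_firth)
  expect_lt(abs(fit$ln_hr - bhat), 1e-3)

  set.seed(101)
  for (i in 1:100) {
    d <- random_small_data()
    cut <- sample(d$marker, 1)
    g <- dichotomize(d, cut)
    if (sum(g$indicator) %in% c(0, d$n)) next
    fit <- fit_cox_binary(d, g)
    f <- if (fit$used_firth)
      function(b) oracle_firth_loglik(d$time, d$event, g$indicator, b)
    else
      function(b) oracle_partial_loglik(d$time, d$event, g$indicator, b)
    bhat <- oracle_grid_argmax(f, -8, 8)
    expect_lt(abs(fit$ln_hr - bhat), 1e-3)
  }
})

test_that("variance equals the inverse numerical observed information", {
  set.seed(7)
  for (i in 1:20) {
    d <- random_small_data(10)
    g <- dichotomize(d, median(d$marker))
    fit <- fit_cox_binary(d, g)
    f <- if (fit$used_firth)
      function(b) oracle_firth_loglik(d$time, d$event, g$indicator, b)
    else
      function(b) oracle_partial_loglik(d$time, d$event, g$indicator, b)
    v <- -1 / oracle_d2(f, fit$ln_hr, h = if (fit$used_firth) 1e-2 else 1e-4)
    expect_lt(abs(fit$variance - v) / v, 0.01)
  }
})

test_that("fit agrees with survival::coxph for both tie methods", {
  set.seed(21)
  checked <- 0
  for (i in 1:40) {
    n <- sample(8:40, 1)
    time <- round(rexp(n, 0.2), 1) + 0.1  # rounding forces ties
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(x) %in% c(0, n) || sum(event) == 0) next
    d <- survival_data(time, event, rnorm(n))
    g <- dichotomize(d, 0); g$indicator <- as.integer(x)
    for (ties in c("efron", "breslow")) {
      cf <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
      if (!is.finite(coef(cf)) || abs(coef(cf)) > 10) next
      fit <- fit_cox_binary(d, g, ties = ties)
      if (fit$used_firth) next
      expect_lt(abs(fit$ln_hr - unname(coef(cf))), 1e-4)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 20)
})

test_that("identical groups give ln_hr = 0 and relabeling negates ln_hr", {
  # two groups with identical (time, event) multisets: symmetric likelihood
  d <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     c(1, 1, 1, 2, 2, 2))
  fit <- fit_cox_binary(d, dichotomize(d, 1.5))
  expect_equal(fit$ln_hr, 0, tolerance = 1e-6)

  set.seed(33)
  d <- random_small_data(12)
  g1 <- dichotomize(d, median(d$marker))
  g2 <- g1; g2$indicator <- 1L - g1$indicator
  f1 <- fit_cox_binary(d, g1)
  f2 <- fit_cox_binary(d, g2)
  expect_equal(f1$ln_hr, -f2$ln_hr, tolerance = 1e-7)
  expect_equal(f1$variance, f2$variance, tolerance = 1e-7)
})

test_that("monotone likelihood triggers Firth and stays finite", {
  # all events in the high group: the MLE diverges
  d <- survival_data(1:5, c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  g <- dichotomize(d, 0.5)
  fit <- fit_cox_binary(d, g)
  expect_true(fit$used_firth)
  expect_true(is.finite(fit$ln_hr))
  bhat <- oracle_grid_argmax(function(b)
    oracle_firth_loglik(d$time, d$event, g$indicator, b), -8, 8)
  expect_lt(abs(fit$ln_hr - bhat), 1e-3)
})

test_that("Firth penalization shrinks estimates toward zero on average", {
  # the Jeffreys penalty is not a strict shrinkage operator for the Cox
  # partial likelihood (small anti-shrinkage is possible), but it shrinks
  # in the typical case and any excursion is small
  set.seed(55)
  shrinkage <- c()
  for (i in 1:40) {
    d <- random_small_data()
    g <- dichotomize(d, median(d$marker))
    if (sum(g$indicator) %in% c(0, d$n)) next
    mle <- tryCatch(fit_cox_binary(d, g), error = function(e) NULL)
    if (is.null(mle) || mle$used_firth || abs(mle$ln_hr) < 1e-6) next
    firth <- fit_cox_firth(d, g)
    shrinkage <- c(shrinkage, abs(mle$ln_hr) - abs(firth$ln_hr))
  }
  expect_gte(length(shrinkage), 15)
  expect_gt(mean(shrinkage > 0), 0.8)
  expect_gt(median(shrinkage), 0)
  expect_lt(max(-shrinkage), 0.2)
})

test_that("Firth fit is symmetric and finite for zero-event groups", {
  d <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     c(1, 1, 1, 2, 2, 2))
  expect_equal(fit_cox_firth(d, dichotomize(d, 1.5))$ln_hr, 0,
               tolerance = 1e-6)
  # high group fully censored
  d <- survival_data(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                     c(0, 0, 0, 1, 1, 1))
  fit <- fit_cox_firth(d, dichotomize(d, 0.5))
  expect_true(is.finite(fit$ln_hr))
  expect_gt(fit$variance, 0)
})

test_that("degenerate inputs raise structured errors", {
  d <- survival_data(1:4, c(0, 0, 0, 0), 1:4)
  expect_error(fit_cox_binary(d, dichotomize(d, 2.5)), "no events")
  d <- survival_data(1:4, c(1, 1, 0, 0), 1:4)
  expect_error(fit_cox_binary(d, dichotomize(d, 10)), "non-empty")
  f <- fit_cox_binary(d, dichotomize(d, 2.5))
  f$converged <- FALSE
  expect_error(wald_chi2(f), "converged")
})

test_that("Wald chi-squared and p-value follow the chi2(1) tail", {
  d <- survival_data(1:4, c(1, 1, 0, 0), 1:4)
  f <- fit_cox_binary(d, dichotomize(d, 2.5))
  f$ln_hr <- 1.0; f$variance <- 0.25
  w <- wald_chi2(f)
  expect_equal(w$chi2, 4.0)
  expect_equal(w$p, oracle_chi2_upper(4.0), tolerance = 1e-10)

  f$ln_hr <- sqrt(qchisq(0.95, 1) * 0.25)
  expect_equal(wald_chi2(f)$p, 0.05, tolerance = 1e-3)

  f$ln_hr <- 0
  w <- wald_chi2(f)
  expect_equal(w$chi2, 0)
  expect_equal(w$p, 1)
})

test_that("Kaplan-Meier estimates follow the product-limit construction", {
  # no censoring: S(t) is the fraction of subjects with time > t
  d <- survival_data(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  km <- km_estimate(d)
  expect_equal(survival_at(km$all, c(0.5, 1, 2.5, 4)),
               c(1, 0.75, 0.5, 0))

  # hand product-limit: S = 2/3 after t=1, 0 after t=3
  d <- survival_data(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3))
  km <- km_estimate(d)
  expect_equal(survival_at(km$all, 2.5), 2 / 3)
  expect_equal(survival_at(km$all, 0.5), 1)  # before the first event

  # per-group curves: survival non-increasing, CI brackets the estimate
  set.seed(9)
  d <- simulate_null_gene(40, 0.3)
  km <- km_estimate(d, dichotomize_at_median(d))
  for (curve in km) {
    expect_true(all(diff(curve$survival) <= 1e-12))
    expect_true(all(curve$ci_lower <= curve$survival + 1e-12))
    expect_true(all(curve$ci_upper >= curve$survival - 1e-12))
    expect_true(all(curve$ci_lower >= 0 & curve$ci_upper <= 1))
  }
  empty <- dichotomize(d, max(d$marker) + 1)
  expect_error(km_estimate(d, empty), "non-empty")
})
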