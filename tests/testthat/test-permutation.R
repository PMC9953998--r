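test_that("adjusted p-value counts exceedances with a zero-count floor", {
  expect_equal(adjusted_pvalue(5, c(rep(1, 963), rep(6, 37))), 0.037)
  expect_equal(adjusted_pvalue(0.1, rep(2, 50)), 1.0)
  expect_equal(adjusted_pvalue(99, rep(1, 100)), 1 / 101)
  expect_equal(adjusted_pvalue(2, c(1, 2, 3)), 2 / 3)  # ties count as >=
  expect_error(adjusted_pvalue(1, numeric(0)), "at least one")
})

test_that("HR adjustment inverts the Wald relation", {
  # p* = 1 maps to the null
  a <- adjust_hr(0.7, 0.3, 1)
  expect_equal(a$hr_star, 1.0)
  expect_equal(a$chi2_star, 0)

  # round trip: p* equal to the unadjusted Wald p returns the same HR
  for (lnhr in c(-1.3, -0.2, 0.4, 2.1)) {
    v <- 0.37
    p_wald <- pchisq(lnhr^2 / v, 1, lower.tail = FALSE)
    a <- adjust_hr(lnhr, v, p_wald)
    expect_equal(log(a$hr_star), lnhr, tolerance = 1e-12)
  }

  # direction preserved, CI log-symmetric with half-width z * sqrt(V)
  a <- adjust_hr(-0.9, 0.2, 0.3)
  expect_lt(a$hr_star, 1)
  hw <- (log(a$ci_upper) - log(a$ci_lower)) / 2
  expect_equal(hw, qnorm(0.975) * sqrt(0.2), tolerance = 1e-12)
  expect_equal(sqrt(a$ci_lower * a$ci_upper), a$hr_star, tolerance = 1e-12)

  expect_error(adjust_hr(1, 0.2, 0), "p_star")
  expect_error(adjust_hr(1, -1, 0.5), "variance")
})

test_that("adjusted CI keeps the unadjusted standard error (printed-table arithmetic)", {
  # Kocak E2F1: unadjusted 6.0 (0.79-46.5) gives SE ~ 1.04; the adjusted
  # estimate 3.8 must carry the same log-scale half-width ~ 2.03
  se <- (log(46.5) - log(0.79)) / (2 * qnorm(0.975))
  expect_equal(se, 1.04, tolerance = 0.01)
  p_star <- 0.08  # any p*; the half-width must not depend on it
  a <- adjust_hr(log(6.0), se^2, p_star)
  hw <- (log(a$ci_upper) - log(a$ci_lower)) / 2
  hw_unadj <- (log(46.5) - log(0.79)) / 2
  expect_equal(hw, hw_unadj, tolerance = 1e-12)
  expect_equal(hw, 2.03, tolerance = 0.02)
})

test_that("hr_star is monotone in p_star and never inflates past the MLE", {
  v <- 0.4
  ps <- seq(0.01, 1, by = 0.01)
  up <- vapply(ps, function(p) adjust_hr(0.8, v, p)$hr_star, numeric(1))
  expect_true(all(diff(up) <= 1e-12))
  dn <- vapply(ps, function(p) adjust_hr(-0.8, v, p)$hr_star, numeric(1))
  expect_true(all(diff(dn) >= -1e-12))

  # whenever p* >= unadjusted Wald p, |ln HR*| <= |ln HR|
  set.seed(4)
  for (i in 1:50) {
    lnhr <- rnorm(1); v <- runif(1, 0.05, 1)
    p_wald <- pchisq(lnhr^2 / v, 1, lower.tail = FALSE)
    p_star <- runif(1, p_wald, 1)
    a <- adjust_hr(lnhr, v, p_star)
    expect_lte(abs(log(a$hr_star)), abs(lnhr) + 1e-9)
  }
})

test_that("permutation null is reproducible and equivariant", {
  set.seed(88)
  d <- simulate_null_gene(25, 0.3)
  p1 <- permutation_null(d, k = 50, seed = 123)
  p2 <- permutation_null(d, k = 50, seed = 123)
  expect_identical(p1$T_star, p2$T_star)
  expect_equal(length(p1$T_star), 50)
  expect_true(all(p1$T_star >= 0))

  # jointly shuffling subjects beforehand leaves T unchanged
  perm <- sample(d$n)
  dp <- survival_data(d$time[perm], d$event[perm], d$marker[perm])
  expect_equal(permutation_null(dp, k = 1, seed = 5)$T, p1$T,
               tolerance = 1e-10)
})

test_that("p* is approximately uniform under the null", {
  set.seed(202)
  p_stars <- replicate(200, {
    d <- simulate_null_gene(30, 0.3)
    permutation_null(d, k = 200)$p_star
  })
  ks <- suppressWarnings(stats::ks.test(p_stars, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("analyze_marker composes the pipeline deterministically", {
  set.seed(61)
  d <- simulate_alt_gene(100, mu1 = 5)$data
  a1 <- analyze_marker(d, k = 500, seed = 17)
  a2 <- analyze_marker(d, k = 500, seed = 17)
  expect_identical(a1$p_star, a2$p_star)
  expect_identical(a1$adjusted$hr_star, a2$adjusted$hr_star)

  # strong true split: significant after adjustment, HR* between 1 and HR
  expect_lt(a1$p_star, 0.01)
  expect_gt(a1$hr, 1)
  expect_gte(a1$hr, a1$adjusted$hr_star)
  expect_gt(a1$adjusted$hr_star, 1)

  dconst <- survival_data(1:4, c(1, 1, 0, 0), rep(1, 4))
  expect_error(analyze_marker(dconst, k = 10), "constant marker")
})
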