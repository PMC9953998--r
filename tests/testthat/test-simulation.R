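test_that("null generator matches the exponential-truncation closed forms", {
  set.seed(12)
  d <- simulate_null_gene(1e5, 0.1)
  expect_equal(mean(d$event), 1 - exp(-1), tolerance = 0.01)
  expect_true(all(d$time <= 10))
  expect_true(all(d$event %in% c(0, 1)))
  expect_equal(mean(d$marker), 4, tolerance = 0.05)
  expect_equal(sd(d$marker), 1, tolerance = 0.05)

  d <- simulate_null_gene(1e5, 0.3)
  expect_equal(mean(d$event), 1 - exp(-3), tolerance = 0.01)
})

test_that("alternative generator produces balanced prognostic classes", {
  set.seed(13)
  g <- simulate_alt_gene(1e5, mu1 = 5)
  expect_equal(sum(g$hidden_labels == 0), sum(g$hidden_labels == 1))
  expect_equal(mean(g$data$marker[g$hidden_labels == 0]), 0,
               tolerance = 0.05)
  expect_equal(mean(g$data$marker[g$hidden_labels == 1]), 5,
               tolerance = 0.05)
  ev0 <- mean(g$data$event[g$hidden_labels == 0])
  ev1 <- mean(g$data$event[g$hidden_labels == 1])
  expect_equal(ev0, 1 - exp(-1), tolerance = 0.01)
  expect_equal(ev1, 1 - exp(-3), tolerance = 0.01)
  expect_error(simulate_alt_gene(21), "even")
})

test_that("null study reports coherent per-cell and pooled metrics", {
  cfg <- null_sim_config(n_genes = 60, sample_sizes = c(20L, 40L),
                         lambda = 0.3, k_permutations = 60L, seed = 5)
  res <- run_null_study(cfg, keep_genes = TRUE)
  expect_equal(nrow(res), 3)  # two cells + pooled
  expect_true(all(res$type1_unadjusted >= 0 & res$type1_unadjusted <= 1))
  pooled <- res[is.na(res$n), ]
  cells <- res[!is.na(res$n), ]
  expect_equal(pooled$n_genes, sum(cells$n_genes))
  genes <- attr(res, "genes")
  expect_equal(nrow(genes), sum(cells$n_genes))
  # pooled type-I error is the gene-weighted mean of the cell rates
  expect_equal(pooled$type1_unadjusted,
               mean(genes$p_lrt <= cfg$alpha))
  # the adjusted estimate is shrunk: selection inflates the unadjusted SD
  expect_true(all(cells$sd_lnhr_adjusted < cells$sd_lnhr_unadjusted))
})

test_that("alt study reports power, validity and central HR metrics", {
  cfg <- alt_sim_config(n_genes = 50, sample_sizes = 20L, mu1 = 5,
                        k_permutations = 100L, seed = 6)
  res <- run_alt_study(cfg, keep_genes = TRUE)
  expect_equal(nrow(res), 1)
  expect_equal(res$expected_hr, expected_optimal_hr(
    binormal_spec(0.1, 0.3, 0, 5)), tolerance = 1e-12)
  expect_true(res$power_adjusted <= res$power_unadjusted)
  expect_true(res$prop_nonvalid >= 0 & res$prop_nonvalid <= 1)
  genes <- attr(res, "genes")
  # non-valid flags mark adjusted estimates beyond the unadjusted ones
  hr <- exp(genes$ln_hr); hrs <- exp(genes$ln_hr_star)
  expect_equal(genes$nonvalid,
               (hr > 1 & hrs > hr) | (hr < 1 & hrs < hr))
})

test_that("unadjusted null ln(HR) distribution shows the selection gap", {
  # selection pushes |ln HR| away from 0: the central mass near zero is
  # far below what a matching normal distribution would put there
  set.seed(44)
  lnhr <- replicate(150, {
    d <- simulate_null_gene(40, 0.3)
    s <- scan_cutoffs(d)
    s$best_fit$ln_hr
  })
  frac_near0 <- mean(abs(lnhr) < 0.1)
  normal_ref <- diff(pnorm(c(-0.1, 0.1), sd = sd(lnhr)))
  expect_lt(frac_near0, normal_ref / 2)
})

test_that("train/test bias summary reproduces the percent-bias arithmetic", {
  # medians of +/- delta map to exp(median) - 1 percent bias
  set.seed(71)
  n <- 101
  tr_lo <- -0.182 + c(rnorm(n - 1, 0, 1e-6), 0)
  tr_hi <- 0.173 + c(rnorm(n - 1, 0, 1e-6), 0)
  s <- train_test_bias_summary(
    train_lnhr = c(tr_lo, tr_hi),
    test_lnhr = rep(0, 2 * n),
    direction = rep(c(-1, 1), each = n))
  expect_equal(s$median_delta, c(-0.182, 0.173), tolerance = 1e-4)
  expect_equal(s$percent_bias, c(-16.6, 18.9), tolerance = 0.05)

  # identical train and test estimates: zero bias in both strata
  x <- rnorm(20)
  s0 <- train_test_bias_summary(x, x, rnorm(20))
  expect_true(all(s0$median_delta == 0))
  expect_true(all(s0$percent_bias == 0))
  expect_true(all(s0$iqr_lower <= s0$median_delta &
                    s0$median_delta <= s0$iqr_upper))
  expect_error(train_test_bias_summary(1:3, 1:2, 1:3), "paired")
})
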