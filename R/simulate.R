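#' Simulate one marker with no survival association (null design)
#'
#' Marker values are i.i.d. Normal(`marker_mean`, `marker_sd`^2),
#' independent of survival; latent event times are exponential with rate
#' `lambda` and right-truncated at `truncation_time`, so subjects whose
#' latent time reaches the cap are censored there.
#'
#' @param n sample size (>= 2).
#' @param lambda exponential event rate per time unit.
#' @param marker_mean,marker_sd marker distribution (defaults 4 and 1).
#' @param truncation_time follow-up cap (default 10 time units).
#' @return A [survival_data] object.
#' @export
simulate_null_gene <- function(n, lambda, marker_mean = 4, marker_sd = 1,
                               truncation_time = 10) {
  stopifnot(n >= 2, lambda > 0, truncation_time > 0)
  marker <- rnorm(n, marker_mean, marker_sd)
  latent <- rexp(n, rate = lambda)
  event <- as.integer(latent < truncation_time)
  time <- pmin(latent, truncation_time)
  survival_data(time = time, event = event, marker = marker)
}

#' Simulate one marker with two hidden prognostic classes (alternative)
#'
#' Balanced hidden classes: n/2 subjects with marker ~ Normal(`mu0`, 1) and
#' event rate `lambda0`, n/2 with marker ~ Normal(`mu1`, 1) and rate
#' `lambda1`; times right-truncated as in [simulate_null_gene()]. The
#' marker carries the prognostic signal only through class membership.
#'
#' @param n even sample size (>= 4).
#' @param mu0,mu1 class marker means (defaults 0 and 1).
#' @param lambda0,lambda1 class event rates (defaults 0.1 and 0.3).
#' @param sigma common class SD (default 1).
#' @param truncation_time follow-up cap (default 10).
#' @return List with `data` (a [survival_data]) and `hidden_labels`
#'   (0/1 class membership, balanced exactly).
#' @export
simulate_alt_gene <- function(n, mu0 = 0, mu1 = 1,
                              lambda0 = 0.1, lambda1 = 0.3,
                              sigma = 1, truncation_time = 10) {
  stopifnot(n >= 4)
  if (n %% 2 != 0)
    stop("balanced hidden classes require an even sample size",
         call. = FALSE)
  half <- n %/% 2
  labels <- c(rep(0L, half), rep(1L, half))
  marker <- rnorm(n, mean = ifelse(labels == 1L, mu1, mu0), sd = sigma)
  latent <- rexp(n, rate = ifelse(labels == 1L, lambda1, lambda0))
  event <- as.integer(latent < truncation_time)
  time <- pmin(latent, truncation_time)
  list(data = survival_data(time, event, marker), hidden_labels = labels)
}

#' Configuration of the null simulation study
#'
#' Defaults are the study conditions of the characterization experiments:
#' 1000 genes per cell, sample sizes 20-100 (step 20) plus 200, marker
#' Normal(4, 1), event rates 0.1 and 0.3, truncation at 10 units, 2000
#' permutations, alpha 0.05.
#'
#' @param n_genes simulated genes per (n, lambda) cell.
#' @param sample_sizes vector of cohort sizes.
#' @param lambda vector of event rates (one study block per rate).
#' @param marker_mean,marker_sd marker distribution.
#' @param truncation_time follow-up cap.
#' @param k_permutations permutation replicates per gene; 0 skips the
#'   permutation calibration (only unadjusted and median metrics).
#' @param alpha nominal significance level.
#' @param min_group_size candidate-split constraint of the scan.
#' @param seed optional master seed.
#' @return A `null_sim_config` list.
#' @export
null_sim_config <- function(n_genes = 1000L,
                            sample_sizes = c(20L, 40L, 60L, 80L, 100L, 200L),
                            lambda = c(0.1, 0.3),
                            marker_mean = 4, marker_sd = 1,
                            truncation_time = 10,
                            k_permutations = 2000L,
                            alpha = 0.05, min_group_size = 8L,
                            seed = NULL) {
  stopifnot(n_genes >= 1, all(sample_sizes >= 2), all(lambda > 0),
            truncation_time > 0, k_permutations >= 0, alpha > 0, alpha < 1)
  structure(list(n_genes = as.integer(n_genes),
                 sample_sizes = as.integer(sample_sizes),
                 lambda = lambda, marker_mean = marker_mean,
                 marker_sd = marker_sd, truncation_time = truncation_time,
                 k_permutations = as.integer(k_permutations),
                 alpha = alpha, min_group_size = as.integer(min_group_size),
                 seed = seed),
            class = "null_sim_config")
}

#' Configuration of the alternative (binormal) simulation study
#'
#' Defaults follow the characterization design: 2000 genes per cell, sample
#' sizes 20, 40, 80, 120, 160, hidden class rates 0.1/0.3, class means 0
#' and `mu1` in {1, 5}, unit SD, truncation at 10 units, 5000 permutations,
#' alpha 0.05, outliers flagged beyond 3x the expected hazard ratio.
#'
#' @param n_genes genes per cell.
#' @param sample_sizes even cohort sizes.
#' @param mu1 vector of class-1 marker means (class 0 fixed at `mu0`).
#' @param mu0 class-0 mean.
#' @param lambda0,lambda1 class event rates.
#' @param sigma common class SD.
#' @param truncation_time follow-up cap.
#' @param k_permutations permutation replicates per gene.
#' @param alpha nominal level.
#' @param outlier_factor unadjusted HRs above `outlier_factor` times the
#'   expected HR are flagged as outliers.
#' @param exclude_flagged drop non-valid and outlier genes from the central
#'   HR summaries (they are always reported as proportions).
#' @param min_group_size scan constraint.
#' @param seed optional master seed.
#' @return An `alt_sim_config` list.
#' @export
alt_sim_config <- function(n_genes = 2000L,
                           sample_sizes = c(20L, 40L, 80L, 120L, 160L),
                           mu1 = c(1, 5), mu0 = 0,
                           lambda0 = 0.1, lambda1 = 0.3, sigma = 1,
                           truncation_time = 10,
                           k_permutations = 5000L,
                           alpha = 0.05, outlier_factor = 3,
                           exclude_flagged = TRUE,
                           min_group_size = 8L, seed = NULL) {
  stopifnot(n_genes >= 1, all(sample_sizes >= 4),
            all(sample_sizes %% 2 == 0), all(mu1 > mu0),
            lambda0 > 0, lambda1 > 0, sigma > 0, truncation_time > 0,
            k_permutations >= 1, outlier_factor > 0)
  structure(list(n_genes = as.integer(n_genes),
                 sample_sizes = as.integer(sample_sizes),
                 mu1 = mu1, mu0 = mu0, lambda0 = lambda0, lambda1 = lambda1,
                 sigma = sigma, truncation_time = truncation_time,
                 k_permutations = as.integer(k_permutations),
                 alpha = alpha, outlier_factor = outlier_factor,
                 exclude_flagged = exclude_flagged,
                 min_group_size = as.integer(min_group_size),
                 seed = seed),
            class = "alt_sim_config")
}

# Low-level per-gene analysis used by both study engines: returns the
# optimal-cutoff estimates, the LR p-value, and (if k > 0) the permutation
# p* and adjusted log hazard ratio.  Uses the C++ entry points directly.
.analyze_gene <- function(d, k, min_group_size) {
  scan <- scan_cutoffs_cpp(d$time, d$event, d$marker,
                           as.integer(min_group_size), TRUE)
  b <- scan$best_index
  if (b == 0L) return(NULL)
  ln_hr <- scan$ln_hr[b]
  v <- scan$variance[b]
  out <- list(ln_hr = ln_hr, variance = v,
              p_lrt = pchisq(scan$lrt[b], 1, lower.tail = FALSE),
              chi2 = scan$chi2[b])
  if (k > 0L) {
    t_star <- perm_max_chi2_cpp(d$time, d$event, d$marker, as.integer(k),
                                as.integer(min_group_size), TRUE)
    p_star <- adjusted_pvalue(scan$chi2[b], t_star)
    chi2_star <- qchisq(p_star, 1, lower.tail = FALSE)
    out$p_star <- p_star
    out$ln_hr_star <- sign(ln_hr) * sqrt(v * chi2_star)
  }
  out
}

.median_gene <- function(d) {
  groups <- dichotomize(d, stats::median(d$marker))
  n1 <- sum(groups$indicator)
  if (n1 == 0L || n1 == d$n) return(NULL)
  fit <- cox_fit_binary_cpp(d$time, d$event, groups$indicator, TRUE, 0L)
  if (!fit$valid) return(NULL)
  list(ln_hr = fit$ln_hr, p_lrt = pchisq(fit$lrt, 1, lower.tail = FALSE))
}

#' Run the null-hypothesis simulation study
#'
#' For each (sample size, event rate) cell, `n_genes` independent null
#' markers are simulated and analysed three ways: the unadjusted
#' optimal-cutoff Cox fit (significance by the likelihood-ratio test), the
#' permutation-adjusted analysis (significance by `p*`, estimate by the
#' bias-corrected log hazard ratio), and the a-priori median-cutoff fit.
#' Reported per cell and pooled per event rate: the three type-I error
#' rates at `alpha` and the across-genes standard deviations of the three
#' log hazard-ratio estimates (all have expectation 0 under the null, so
#' the SD measures the overestimation bias directly).
#'
#' @param config a [null_sim_config()].
#' @param keep_genes attach the per-gene estimates as attribute `"genes"`.
#' @return Data frame with one row per cell plus a pooled row per event
#'   rate (`n = NA`), columns `lambda`, `n`, `n_genes`, `n_dropped`,
#'   `type1_unadjusted`, `type1_adjusted`, `type1_median`,
#'   `sd_lnhr_unadjusted`, `sd_lnhr_adjusted`, `sd_lnhr_median`.
#' @export
run_null_study <- function(config = null_sim_config(), keep_genes = FALSE) {
  stopifnot(inherits(config, "null_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$k_permutations
  rows <- list()
  genes_all <- list()
  for (lam in config$lambda) {
    for (n in config$sample_sizes) {
      recs <- vector("list", config$n_genes)
      dropped <- 0L
      for (g in seq_len(config$n_genes)) {
        d <- simulate_null_gene(n, lam, config$marker_mean,
                                config$marker_sd, config$truncation_time)
        opt <- tryCatch(.analyze_gene(d, k, config$min_group_size),
                        error = function(e) NULL)
        med <- .median_gene(d)
        if (is.null(opt) || is.null(med)) {
          dropped <- dropped + 1L
          next
        }
        recs[[g]] <- data.frame(
          lambda = lam, n = n,
          ln_hr = opt$ln_hr, p_lrt = opt$p_lrt,
          p_star = if (k > 0L) opt$p_star else NA_real_,
          ln_hr_star = if (k > 0L) opt$ln_hr_star else NA_real_,
          ln_hr_median = med$ln_hr, p_median = med$p_lrt)
      }
      genes <- do.call(rbind, recs)
      genes_all[[length(genes_all) + 1L]] <- genes
      rows[[length(rows) + 1L]] <- .null_metrics(genes, lam, n,
                                                 dropped, config$alpha)
    }
    # pooled row for this event rate
    pool <- do.call(rbind, genes_all[vapply(genes_all, function(g)
      g$lambda[1] == lam, logical(1))])
    rows[[length(rows) + 1L]] <- .null_metrics(pool, lam, NA_integer_,
                                               0L, config$alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_genes)
    attr(out, "genes") <- do.call(rbind, genes_all)
  out
}

.null_metrics <- function(genes, lam, n, dropped, alpha) {
  data.frame(
    lambda = lam, n = n, n_genes = nrow(genes), n_dropped = dropped,
    type1_unadjusted = mean(genes$p_lrt <= alpha),
    type1_adjusted = mean(genes$p_star <= alpha),
    type1_median = mean(genes$p_median <= alpha),
    sd_lnhr_unadjusted = sd(genes$ln_hr),
    sd_lnhr_adjusted = sd(genes$ln_hr_star),
    sd_lnhr_median = sd(genes$ln_hr_median))
}

#' Run the alternative-hypothesis (binormal) simulation study
#'
#' For each (sample size, class separation) cell, `n_genes` markers with
#' two hidden prognostic classes are simulated and analysed at the optimal
#' cut-off with permutation calibration. Reported per cell: power of the
#' adjusted (`p* <= alpha`) and unadjusted (LR test) analyses, the
#' proportion of non-valid adjusted estimates (adjusted value further from
#' the null than the unadjusted one), the proportion of outliers
#' (unadjusted HR above `outlier_factor` times the expected HR), central
#' (median) adjusted and unadjusted HRs, and the closed-form expected HR
#' at the optimal discriminant threshold.
#'
#' @param config an [alt_sim_config()].
#' @param keep_genes attach per-gene estimates as attribute `"genes"`.
#' @return Data frame with one row per (mu1, n) cell.
#' @export
run_alt_study <- function(config = alt_sim_config(), keep_genes = FALSE) {
  stopifnot(inherits(config, "alt_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$k_permutations
  rows <- list()
  genes_all <- list()
  for (mu1 in config$mu1) {
    spec <- binormal_spec(config$lambda0, config$lambda1,
                          config$mu0, mu1, config$sigma, config$sigma)
    ehr <- expected_optimal_hr(spec)
    for (n in config$sample_sizes) {
      recs <- vector("list", config$n_genes)
      dropped <- 0L
      for (g in seq_len(config$n_genes)) {
        d <- simulate_alt_gene(n, config$mu0, mu1, config$lambda0,
                               config$lambda1, config$sigma,
                               config$truncation_time)$data
        opt <- tryCatch(.analyze_gene(d, k, config$min_group_size),
                        error = function(e) NULL)
        if (is.null(opt)) {
          dropped <- dropped + 1L
          next
        }
        recs[[g]] <- data.frame(mu1 = mu1, n = n,
                                ln_hr = opt$ln_hr, p_lrt = opt$p_lrt,
                                p_star = opt$p_star,
                                ln_hr_star = opt$ln_hr_star)
      }
      genes <- do.call(rbind, recs)
      hr <- exp(genes$ln_hr)
      hr_star <- exp(genes$ln_hr_star)
      nonvalid <- (hr > 1 & hr_star > hr) | (hr < 1 & hr_star < hr)
      outlier <- hr > config$outlier_factor * ehr
      central_idx <- if (config$exclude_flagged) !(nonvalid | outlier)
                     else rep(TRUE, nrow(genes))
      genes$nonvalid <- nonvalid
      genes$outlier <- outlier
      genes_all[[length(genes_all) + 1L]] <- genes
      rows[[length(rows) + 1L]] <- data.frame(
        mu1 = mu1, n = n, n_genes = nrow(genes), n_dropped = dropped,
        power_adjusted = mean(genes$p_star <= config$alpha),
        power_unadjusted = mean(genes$p_lrt <= config$alpha),
        prop_nonvalid = mean(nonvalid),
        prop_outliers = mean(outlier),
        central_hr_adjusted = median(hr_star[central_idx]),
        central_hr_unadjusted = median(hr[central_idx]),
        expected_hr = ehr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_genes)
    attr(out, "genes") <- do.call(rbind, genes_all)
  out
}

#' Summarize train/test differences of log hazard ratios
#'
#' Internal-validation summary: for paired per-gene estimates from a
#' training and a test set, the difference `delta = ln HR_train -
#' ln HR_test` measures the optimism of the training-set estimate.
#' Medians and interquartile ranges are reported separately for genes with
#' whole-data HR <= 1 and > 1 (direction taken from a Cox coefficient on
#' the full data, supplied by the caller), and the percent bias is
#' `100 * (exp(median delta) - 1)`.
#'
#' @param train_lnhr,test_lnhr paired per-gene log hazard ratios.
#' @param direction per-gene whole-data log hazard ratio (or any numeric
#'   whose sign assigns the stratum: > 0 means "HR > 1").
#' @return Data frame with one row per stratum: `stratum`, `n_genes`,
#'   `median_delta`, `iqr_lower`, `iqr_upper`, `percent_bias`.
#' @examples
#' train_test_bias_summary(c(0.5, -0.4), c(0.3, -0.2), c(1, -1))
#' @export
train_test_bias_summary <- function(train_lnhr, test_lnhr, direction) {
  if (length(train_lnhr) != length(test_lnhr) ||
      length(train_lnhr) != length(direction))
    stop("train, test and direction vectors must be paired per gene",
         call. = FALSE)
  delta <- train_lnhr - test_lnhr
  stratum <- ifelse(direction > 0, "HR>1", "HR<=1")
  out <- lapply(c("HR<=1", "HR>1"), function(s) {
    d <- delta[stratum == s]
    if (length(d) == 0L) return(NULL)
    q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stratum = s, n_genes = length(d), median_delta = q[2],
               iqr_lower = q[1], iqr_upper = q[3],
               percent_bias = 100 * (exp(q[2]) - 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
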