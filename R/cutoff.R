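#' Exhaustive cut-point scan maximizing the Wald statistic
#'
#' Runs the "running" procedure: every distinct observed marker value whose
#' split (`marker > c` vs `marker <= c`) leaves at least `min_group_size`
#' subjects in each group is a candidate cut-off; for each, the binary Cox
#' model is fitted (with automatic Firth fallback for degenerate event
#' patterns) and the Wald chi-squared recorded. The cut-off with the largest
#' statistic is retained; exact ties are broken toward the smallest cut-off
#' so the scan is deterministic.
#'
#' The selected statistic `T` is, by construction, the maximum of many
#' looks at the same data and therefore biased; see [permutation_null()]
#' and [adjust_hr()] for its calibration.
#'
#' @param data a [survival_data] object with at least two distinct marker
#'   values.
#' @param min_group_size minimum subjects per group for a candidate split.
#'   The default of 8 excludes near-degenerate splits whose estimates are
#'   dominated by a handful of subjects; set to 1 to scan every observed
#'   value (the Firth fallback keeps even 1-vs-(n-1) splits finite). See
#'   the methods vignette for how this default was fixed.
#' @param ties tie-handling method passed to the Cox fits.
#' @return A `cutoff_scan`: list with `cutoffs`, `statistic_per_cutoff`
#'   (Wald chi-squared, NA where no finite fit exists), `best_cutoff`,
#'   `best_fit` (a `binary_cox_fit`), and `T` (the maximal statistic).
#' @examples
#' set.seed(1)
#' d <- simulate_null_gene(30, lambda = 0.3)
#' s <- scan_cutoffs(d)
#' s$best_cutoff; s$T
#' @export
scan_cutoffs <- function(data, min_group_size = 8L,
                         ties = c("efron", "breslow")) {
  stopifnot(inherits(data, "survival_data"))
  ties <- match.arg(ties)
  min_group_size <- as.integer(min_group_size)
  if (min_group_size < 1L)
    stop("min_group_size must be >= 1", call. = FALSE)
  if (length(unique(data$marker)) < 2L)
    stop("constant marker: no valid cut-off", call. = FALSE)
  if (sum(data$event) == 0L)
    stop("no events observed: hazard ratio is not estimable", call. = FALSE)
  res <- scan_cutoffs_cpp(data$time, data$event, data$marker,
                          min_group_size, ties == "efron")
  if (length(res$cutoffs) == 0L)
    stop("no candidate split satisfies min_group_size", call. = FALSE)
  if (res$best_index == 0L || all(is.na(res$chi2)))
    stop("no candidate cut-off admitted a finite Cox fit", call. = FALSE)
  best <- res$best_index
  best_cutoff <- res$cutoffs[best]
  best_fit <- .cox_binary(data, dichotomize(data, best_cutoff),
                          efron = ties == "efron", firth = 0L)
  structure(list(cutoffs = res$cutoffs,
                 statistic_per_cutoff = res$chi2,
                 lrt_per_cutoff = res$lrt,
                 best_cutoff = best_cutoff,
                 best_fit = best_fit,
                 T = res$chi2[best],
                 min_group_size = min_group_size,
                 ties = ties),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("cutoff_scan: ", length(x$cutoffs), " candidate cut-offs\n", sep = "")
  cat("  best cut-off ", format(x$best_cutoff), " with Wald chi2 = ",
      format(x$T, digits = 4),
      if (isTRUE(x$best_fit$used_firth)) "  [Firth]", "\n", sep = "")
  invisible(x)
}
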