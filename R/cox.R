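#' Cox proportional-hazards fit for a single binary group indicator
#'
#' Maximizes the partial likelihood over the scalar log hazard ratio of the
#' high vs low group by safeguarded Newton iteration (start 0, score
#' tolerance 1e-8, step halving on likelihood decrease). If either group has
#' no events, or the Newton iteration diverges (monotone partial
#' likelihood), the fit automatically falls back to the Firth-penalized
#' likelihood and flags `used_firth = TRUE`, so a finite estimate is always
#' returned for non-degenerate groups.
#'
#' @param data a [survival_data] object.
#' @param groups a `group_assignment` (see [dichotomize()]); both groups
#'   must be non-empty.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @return A `binary_cox_fit`: list with `ln_hr`, `variance`, `used_firth`,
#'   `converged`, `n_events_high`, `n_events_low`, `loglik`, `loglik0`,
#'   `lrt` (likelihood-ratio statistic vs beta = 0) and `chi2` (Wald).
#' @seealso [fit_cox_firth()] to force the penalized fit, [wald_chi2()].
#' @export
fit_cox_binary <- function(data, groups, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .cox_binary(data, groups, efron = ties == "efron", firth = 0L)
}

#' Firth-penalized Cox fit for a binary group indicator
#'
#' Maximizes the penalized partial log-likelihood `l(beta) + log(I(beta))/2`
#' (Jeffreys invariant prior on the scalar information), which has a finite
#' maximum even under monotone likelihood, e.g. when one group has no
#' events. The variance is the inverse penalized observed information.
#'
#' @inheritParams fit_cox_binary
#' @return A `binary_cox_fit` with `used_firth = TRUE`.
#' @export
fit_cox_firth <- function(data, groups, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .cox_binary(data, groups, efron = ties == "efron", firth = 1L)
}

.cox_binary <- function(data, groups, efron, firth) {
  stopifnot(inherits(data, "survival_data"),
            inherits(groups, "group_assignment"))
  x <- groups$indicator
  if (length(x) != data$n)
    stop("group assignment length does not match data", call. = FALSE)
  n1 <- sum(x)
  if (n1 == 0L || n1 == data$n)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(data$event) == 0L)
    stop("no events observed: hazard ratio is not estimable", call. = FALSE)
  res <- cox_fit_binary_cpp(data$time, data$event, as.integer(x),
                            efron, as.integer(firth))
  if (!res$valid)
    stop("Cox fit failed to produce a finite estimate", call. = FALSE)
  structure(list(ln_hr = res$ln_hr, variance = res$variance,
                 used_firth = res$used_firth, converged = res$converged,
                 n_events_high = res$n_events_high,
                 n_events_low = res$n_events_low,
                 loglik = res$loglik, loglik0 = res$loglik0,
                 lrt = res$lrt, chi2 = res$chi2,
                 cutoff = groups$cutoff, ties = if (efron) "efron" else "breslow"),
            class = "binary_cox_fit")
}

#' @export
print.binary_cox_fit <- function(x, ...) {
  z <- qnorm(0.975)
  cat("binary_cox_fit: HR = ", format(exp(x$ln_hr), digits = 3),
      " (95% CI ", format(exp(x$ln_hr - z * sqrt(x$variance)), digits = 3),
      "-", format(exp(x$ln_hr + z * sqrt(x$variance)), digits = 3), ")",
      if (isTRUE(x$used_firth)) "  [Firth]", "\n", sep = "")
  cat("  events high/low: ", x$n_events_high, "/", x$n_events_low,
      "; Wald chi2 = ", format(x$chi2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Wald test of a binary Cox fit
#'
#' `chi2 = ln_hr^2 / variance`, compared with the chi-squared distribution
#' on one degree of freedom; this Wald relation is what the bias-corrected
#' estimate inverts.
#'
#' @param fit a `binary_cox_fit`.
#' @return List with `chi2` and the upper-tail `p`.
#' @export
wald_chi2 <- function(fit) {
  stopifnot(inherits(fit, "binary_cox_fit"))
  if (!isTRUE(fit$converged))
    stop("Wald test requires a converged fit", call. = FALSE)
  chi2 <- fit$ln_hr^2 / fit$variance
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier estimates per group
#'
#' Product-limit survival estimates with Greenwood variance and pointwise
#' 95% confidence bands (log scale by default, clipped to \[0, 1\]),
#' computed via [survival::survfit()]. Curves are right-continuous step
#' functions; use [survival_at()] to read them at arbitrary times.
#'
#' @param data a [survival_data] object.
#' @param groups optional `group_assignment`; when `NULL` a single curve for
#'   the whole cohort is returned.
#' @param conf_type `"log"` (default) or `"log-log"` confidence transform.
#' @return A named list of `km_curve` objects (`low`, `high`, or `all`),
#'   each with `event_times`, `survival`, `ci_lower`, `ci_upper`, `n_risk`,
#'   `n_event`.
#' @export
km_estimate <- function(data, groups = NULL, conf_type = c("log", "log-log")) {
  stopifnot(inherits(data, "survival_data"))
  conf_type <- match.arg(conf_type)
  df <- data.frame(time = data$time, event = data$event)
  if (is.null(groups)) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                            conf.type = conf_type)
    return(list(all = .km_curve(sf)))
  }
  stopifnot(inherits(groups, "group_assignment"))
  if (sum(groups$indicator) == 0L || sum(groups$indicator) == data$n)
    stop("both groups must be non-empty for per-group curves", call. = FALSE)
  df$grp <- factor(ifelse(groups$indicator == 1L, "high", "low"),
                   levels = c("low", "high"))
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = df,
                          conf.type = conf_type)
  pieces <- .split_survfit(sf)
  lapply(pieces, .km_curve)
}

.split_survfit <- function(sf) {
  strata <- rep(names(sf$strata), sf$strata)
  out <- list()
  for (s in names(sf$strata)) {
    idx <- strata == s
    piece <- list(time = sf$time[idx], surv = sf$surv[idx],
                  lower = sf$lower[idx], upper = sf$upper[idx],
                  n.risk = sf$n.risk[idx], n.event = sf$n.event[idx])
    out[[sub("^grp=", "", s)]] <- piece
  }
  out
}

.km_curve <- function(sf) {
  lo <- pmin(pmax(ifelse(is.na(sf$lower), 0, sf$lower), 0), 1)
  hi <- pmin(pmax(ifelse(is.na(sf$upper), 1, sf$upper), 0), 1)
  structure(list(event_times = sf$time, survival = sf$surv,
                 ci_lower = lo, ci_upper = hi,
                 n_risk = sf$n.risk, n_event = sf$n.event),
            class = "km_curve")
}

#' Read a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step convention: `survival_at(curve, t)` is the estimate
#' just after the last event time at or before `t`, and 1 before the first
#' recorded time.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t numeric vector of times.
#' @return Numeric vector of survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  f <- stats::stepfun(curve$event_times, c(1, curve$survival), right = FALSE)
  f(t)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("km_curve: ", length(x$event_times), " time points, final S = ",
      format(utils::tail(x$survival, 1), digits = 3), "\n", sep = "")
  invisible(x)
}
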