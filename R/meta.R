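#' DerSimonian-Laird random-effects pooling of hazard ratios
#'
#' Pools per-cohort hazard ratios (with 95% confidence intervals) on the
#' log scale. Standard errors are recovered from the intervals assuming
#' log-symmetric Wald limits, `se = (ln upper - ln lower) / (2 z)`. The
#' between-study variance is the method-of-moments estimate
#' `tau2 = max(0, (Q - (m - 1)) / (sum w - sum w^2 / sum w))` with
#' fixed-effect weights `w = 1/se^2`, and the pooled estimate uses
#' random-effects weights `1 / (se^2 + tau2)`. No small-sample
#' (Knapp-Hartung) correction is applied.
#'
#' @param studies data frame with columns `hr`, `ci_lower`, `ci_upper` and
#'   optionally `label`.
#' @param conf_level confidence level of both the inputs and the pooled
#'   interval (default 0.95).
#' @param z_value normal quantile used to recover the standard errors and
#'   build the pooled interval; defaults to the exact `qnorm` value, set
#'   `1.96` to replicate hand calculations from printed tables.
#' @return A `meta_result`: `m_hr`, `ci_lower`, `ci_upper`, `tau2`, `Q`,
#'   normalized `weights`, and the per-study `ln_hr` and `se`.
#' @examples
#' studies <- data.frame(hr = c(6.0, 4.6, 5.9),
#'                       ci_lower = c(0.79, 1.0, 0.76),
#'                       ci_upper = c(46.5, 20.8, 45.4))
#' dersimonian_laird(studies)   # pooled 5.3 (1.9-15.0)
#' @export
dersimonian_laird <- function(studies, conf_level = 0.95, z_value = NULL) {
  if (is.null(studies) || nrow(studies) == 0L)
    stop("at least one study is required", call. = FALSE)
  stopifnot(all(c("hr", "ci_lower", "ci_upper") %in% names(studies)))
  z <- if (is.null(z_value)) qnorm(1 - (1 - conf_level) / 2) else z_value
  if (any(studies$ci_lower >= studies$hr | studies$hr >= studies$ci_upper))
    warning("printed rounding: some HR lies outside (ci_lower, ci_upper)")
  y <- log(studies$hr)
  se <- (log(studies$ci_upper) - log(studies$ci_lower)) / (2 * z)
  if (any(!is.finite(se) | se <= 0))
    stop("every study needs a finite positive standard error", call. = FALSE)
  m <- length(y)
  w <- 1 / se^2
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  tau2 <- if (m == 1L) 0 else
    max(0, (Q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  y_re <- sum(ws * y) / sum(ws)
  se_re <- 1 / sqrt(sum(ws))
  structure(list(m_hr = exp(y_re),
                 ci_lower = exp(y_re - z * se_re),
                 ci_upper = exp(y_re + z * se_re),
                 tau2 = tau2, Q = Q,
                 weights = ws / sum(ws),
                 ln_hr = y, se = se,
                 labels = if ("label" %in% names(studies))
                   as.character(studies$label) else NULL,
                 conf_level = conf_level, z = z),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("meta_result (DerSimonian-Laird, ", length(x$ln_hr), " studies)\n",
      sep = "")
  cat("  pooled HR = ", format(x$m_hr, digits = 3), " (",
      format(100 * x$conf_level), "% CI ",
      format(x$ci_lower, digits = 3), "-",
      format(x$ci_upper, digits = 3), ")\n", sep = "")
  cat("  tau2 = ", format(x$tau2, digits = 4), ", Q = ",
      format(x$Q, digits = 4), "\n", sep = "")
  invisible(x)
}
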