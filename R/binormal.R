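#' Specification of a binormal two-rate marker model
#'
#' Two hidden patient classes: class 0 with marker ~ Normal(mu0, sigma0^2)
#' and constant event rate lambda0, class 1 with marker ~ Normal(mu1,
#' sigma1^2) and rate lambda1. Because within-class hazards are constant
#' (exponential event times), the ratio of event rates above vs below a
#' threshold equals the hazard ratio of the corresponding split.
#'
#' @param lambda0,lambda1 positive event rates (per time unit).
#' @param mu0,mu1 class means of the marker.
#' @param sigma0,sigma1 positive class standard deviations.
#' @param mix fraction of subjects in class 0 (only the balanced case 0.5
#'   supports the closed-form expected hazard ratio).
#' @return A `binormal_spec` object.
#' @export
binormal_spec <- function(lambda0, lambda1, mu0, mu1,
                          sigma0 = 1, sigma1 = 1, mix = 0.5) {
  if (lambda0 <= 0 || lambda1 <= 0)
    stop("event rates must be strictly positive", call. = FALSE)
  if (sigma0 <= 0 || sigma1 <= 0)
    stop("standard deviations must be strictly positive", call. = FALSE)
  if (mix <= 0 || mix >= 1)
    stop("mix must lie in (0, 1)", call. = FALSE)
  structure(list(lambda0 = lambda0, lambda1 = lambda1,
                 mu0 = mu0, mu1 = mu1,
                 sigma0 = sigma0, sigma1 = sigma1, mix = mix),
            class = "binormal_spec")
}

#' @export
print.binormal_spec <- function(x, ...) {
  cat("binormal_spec: rates (", x$lambda0, ", ", x$lambda1,
      "), means (", x$mu0, ", ", x$mu1, "), SDs (", x$sigma0, ", ",
      x$sigma1, "), mix ", x$mix, "\n", sep = "")
  invisible(x)
}

#' Optimal discriminant threshold of a binormal marker
#'
#' The theoretically best split point of two equally weighted normal
#' components with equal variances: the midpoint of the class means.
#'
#' @param spec a [binormal_spec].
#' @return `(mu0 + mu1) / 2`.
#' @export
optimal_discriminant_threshold <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  (spec$mu0 + spec$mu1) / 2
}

#' Expected hazard ratio at the optimal discriminant threshold
#'
#' Closed form for the true hazard ratio of the split `marker > ODT` vs
#' `marker <= ODT` under the balanced binormal two-rate model. With
#' `Phi_i = pnorm((ODT - mu_i) / sigma_i)` the fraction of class i falling
#' below the threshold, the event rate above the threshold is
#' `lambda0 (1 - Phi0) + lambda1 (1 - Phi1)` per unit mixture mass and the
#' rate below is `lambda0 Phi0 + lambda1 Phi1`, so
#'
#' `HRopt = (lambda0 + lambda1) / (lambda0 Phi0 + lambda1 Phi1) - 1`.
#'
#' Constant within-class hazards make this rate ratio exactly the hazard
#' ratio. Only the balanced mixture (`mix = 0.5`) is supported; the
#' closed form does not extend to unbalanced mixtures.
#'
#' @param spec a [binormal_spec] with `mix = 0.5`.
#' @return The expected hazard ratio (positive real).
#' @examples
#' expected_optimal_hr(binormal_spec(0.1, 0.3, 0, 1))  # 1.47
#' expected_optimal_hr(binormal_spec(0.1, 0.3, 0, 5))  # 2.95
#' @export
expected_optimal_hr <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  if (spec$mix != 0.5)
    stop("the closed form requires a balanced mixture (mix = 0.5)",
         call. = FALSE)
  odt <- optimal_discriminant_threshold(spec)
  phi0 <- pnorm((odt - spec$mu0) / spec$sigma0)
  phi1 <- pnorm((odt - spec$mu1) / spec$sigma1)
  above <- spec$lambda0 * (1 - phi0) + spec$lambda1 * (1 - phi1)
  below <- spec$lambda0 * phi0 + spec$lambda1 * phi1
  above / below
}
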