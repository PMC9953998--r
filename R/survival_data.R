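#' Construct a survival dataset for one cohort and one marker
#'
#' Bundles aligned vectors of follow-up time, event indicator and marker
#' value, validating the invariants every downstream operation relies on:
#' strictly positive times, a strictly 0/1 event indicator, no missing
#' values, and at least two subjects.
#'
#' @param time positive follow-up times (arbitrary units).
#' @param event event indicator, 1 = event observed, 0 = censored.
#' @param marker real-valued marker (e.g. gene expression).
#' @return An object of class `survival_data` with elements `time`, `event`,
#'   `marker` and `n`.
#' @examples
#' d <- survival_data(time = c(2, 5, 3), event = c(1, 0, 1),
#'                    marker = c(0.3, 1.2, -0.5))
#' d$n
#' @export
survival_data <- function(time, event, marker) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  marker <- as.numeric(marker)
  n <- length(time)
  if (n < 2L)
    stop("survival_data needs at least 2 subjects", call. = FALSE)
  if (length(event) != n || length(marker) != n)
    stop("time, event and marker must have equal length", call. = FALSE)
  if (anyNA(time) || anyNA(event) || anyNA(marker))
    stop("missing values are not allowed in survival_data", call. = FALSE)
  if (any(time <= 0))
    stop("all follow-up times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  structure(list(time = time, event = as.integer(event),
                 marker = marker, n = n),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat("survival_data: ", x$n, " subjects, ", sum(x$event), " events\n",
      sep = "")
  cat("  time   range: [", format(min(x$time)), ", ",
      format(max(x$time)), "]\n", sep = "")
  cat("  marker range: [", format(min(x$marker)), ", ",
      format(max(x$marker)), "]\n", sep = "")
  invisible(x)
}

#' Split a cohort at a marker cut-off
#'
#' The high group is `marker > cutoff` (half-open convention), so every
#' observed marker value is a usable threshold and the maximum observed
#' value never yields an empty low group.
#'
#' @param data a [survival_data] object.
#' @param cutoff threshold on the marker scale.
#' @return A `group_assignment`: list with `indicator` (1 = high group) and
#'   `cutoff`.
#' @export
dichotomize <- function(data, cutoff) {
  stopifnot(inherits(data, "survival_data"))
  structure(list(indicator = as.integer(data$marker > cutoff),
                 cutoff = as.numeric(cutoff)),
            class = "group_assignment")
}

#' Split a cohort at the sample median of the marker
#'
#' The cut-off is the sample median (for even n, the midpoint of the two
#' central order statistics). Subjects with marker equal to the median fall
#' in the low ("at-or-below") group.
#'
#' @param data a [survival_data] object with at least two distinct marker
#'   values.
#' @return A `group_assignment` at the median cut-off.
#' @examples
#' d <- survival_data(1:4, c(1, 1, 0, 1), marker = c(1, 2, 3, 4))
#' dichotomize_at_median(d)$cutoff  # 2.5
#' @export
dichotomize_at_median <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (length(unique(data$marker)) < 2L)
    stop("constant marker: no valid cut-off", call. = FALSE)
  dichotomize(data, stats::median(data$marker))
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment: cutoff ", format(x$cutoff), "; high n = ",
      sum(x$indicator), ", low n = ", sum(1 - x$indicator), "\n", sep = "")
  invisible(x)
}
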