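#' Read one or more cohorts from a delimited patient-level table
#'
#' Expects a comma-delimited file with a header containing a follow-up time
#' column, a 0/1 event column, one or more numeric marker columns, and
#' optionally a cohort label column for multi-study files. Rows failing
#' validation are rejected with row-numbered diagnostics.
#'
#' @param path file path.
#' @param time_col,event_col,cohort_col column names (set `cohort_col` to
#'   `NULL` or name a column absent from the file for single-cohort data).
#' @param marker_cols marker column names; `NULL` takes every remaining
#'   numeric column.
#' @return Named list (one element per cohort, in order of first
#'   appearance) of named lists of [survival_data] objects, one per marker.
#' @export
read_cohorts <- function(path, time_col = "time", event_col = "event",
                         marker_cols = NULL, cohort_col = "cohort") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L)
    stop("no usable rows in ", path, call. = FALSE)
  for (col in c(time_col, event_col))
    if (!col %in% names(tab))
      stop("missing required column '", col, "' in ", path, call. = FALSE)
  has_cohort <- !is.null(cohort_col) && cohort_col %in% names(tab)
  if (is.null(marker_cols)) {
    drop <- c(time_col, event_col, if (has_cohort) cohort_col)
    marker_cols <- setdiff(names(tab), drop)
    marker_cols <- marker_cols[vapply(tab[marker_cols], is.numeric,
                                      logical(1))]
  }
  if (length(marker_cols) == 0L)
    stop("no numeric marker columns found in ", path, call. = FALSE)

  time <- suppressWarnings(as.numeric(tab[[time_col]]))
  event <- suppressWarnings(as.numeric(tab[[event_col]]))
  bad <- which(is.na(time) | time <= 0 | is.na(event) |
                 !(event %in% c(0, 1)))
  for (mc in marker_cols)
    bad <- union(bad, which(is.na(suppressWarnings(
      as.numeric(tab[[mc]])))))
  if (length(bad) > 0L)
    stop("malformed rows (1-based, excluding header): ",
         paste(sort(bad), collapse = ", "), call. = FALSE)

  cohorts <- if (has_cohort) as.character(tab[[cohort_col]])
             else rep("cohort", nrow(tab))
  out <- list()
  for (cl in unique(cohorts)) {
    idx <- cohorts == cl
    out[[cl]] <- lapply(stats::setNames(marker_cols, marker_cols),
                        function(mc)
                          survival_data(time[idx], event[idx],
                                        as.numeric(tab[[mc]][idx])))
  }
  out
}

#' Write a simulated cohort table to disk
#'
#' Re-exposes the simulation generators as a data-file writer so that the
#' rest of the tool chain (and external tools) can ingest the same
#' designs. Output is byte-identical for identical seeds.
#'
#' @param kind `"null"` (no marker-survival association), `"alt"` (two
#'   hidden prognostic classes) or `"cohort"` (three null cohorts in one
#'   multi-study file).
#' @param n subjects per cohort.
#' @param path output CSV path.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @param ... passed to [simulate_null_gene()] or [simulate_alt_gene()]
#'   (e.g. `lambda`, `mu1`).
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind = c("null", "alt", "cohort"), n, path,
                             seed, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  fmt <- function(d, extra = NULL) {
    df <- data.frame(time = round(d$time, 6), event = d$event,
                     marker = round(d$marker, 6))
    if (!is.null(extra)) df <- cbind(df, extra)
    df
  }
  df <- switch(kind,
    null = fmt(simulate_null_gene(n, ...)),
    alt = {
      g <- simulate_alt_gene(n, ...)
      fmt(g$data, data.frame(hidden_class = g$hidden_labels))
    },
    cohort = do.call(rbind, lapply(c("A", "B", "C"), function(cl) {
      d <- simulate_null_gene(n, ...)
      cbind(fmt(d), data.frame(cohort = cl))
    })))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an analysis, simulation or meta-analysis result
#'
#' JSON output (via jsonlite) round-trips the full record including a
#' provenance block (package version, seed, configuration echo); CSV
#' output writes the tabular part (simulation metrics, or a one-row table
#' for single-marker and meta-analysis results).
#'
#' @param record a `marker_analysis`, `meta_result`, or a simulation
#'   metrics data frame from [run_null_study()]/[run_alt_study()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(record, path, format = c("json", "csv")) {
  format <- match.arg(format)
  tab <- .as_report_table(record)
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(
    package = "cutadjust",
    version = as.character(packageVersion("cutadjust")),
    record_class = class(record)[1],
    record = .strip_for_json(record),
    table = tab)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.strip_for_json <- function(record) {
  if (inherits(record, "marker_analysis")) {
    record$fit <- unclass(record$fit)
    record$adjusted <- unclass(record$adjusted)
    return(unclass(record))
  }
  if (inherits(record, "meta_result")) return(unclass(record))
  record
}

.as_report_table <- function(record) {
  if (is.data.frame(record)) return(record)
  if (inherits(record, "marker_analysis"))
    return(data.frame(best_cutoff = record$best_cutoff,
                      hr = record$hr, ci_lower = record$ci_lower,
                      ci_upper = record$ci_upper, p_lrt = record$p_lrt,
                      p_star = record$p_star,
                      hr_adjusted = record$adjusted$hr_star,
                      ci_lower_adjusted = record$adjusted$ci_lower,
                      ci_upper_adjusted = record$adjusted$ci_upper,
                      k = record$k))
  if (inherits(record, "meta_result"))
    return(data.frame(m_hr = record$m_hr, ci_lower = record$ci_lower,
                      ci_upper = record$ci_upper, tau2 = record$tau2,
                      Q = record$Q, n_studies = length(record$ln_hr)))
  stop("unsupported record type: ", class(record)[1], call. = FALSE)
}

#' Read back a JSON report
#'
#' @param path a file written by [write_report()] in JSON format.
#' @return The parsed payload list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
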