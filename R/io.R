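# Reading and validating per-site subject tables, and writing result tables.

.time_unit_days <- c(days = 1, weeks = 7, months = 30.44, years = 365.25)

#' Describe the columns of a site's survival table
#'
#' @param time_col Name of the duration column.
#' @param event_col Name of the event indicator column (1 = event,
#'   0 = censored; `TRUE`/`FALSE` and `"0"`/`"1"` are also accepted).
#' @param group_col Optional name of a cohort/group column (log-rank).
#' @param covariate_cols Character vector of numeric covariate columns (Cox).
#' @param time_unit Unit the time column is recorded in; one of `"days"`,
#'   `"weeks"`, `"months"`, `"years"`. Durations are converted to the
#'   study's canonical unit on read with the factors weeks = 7,
#'   months = 30.44 and years = 365.25 days.
#' @return An object of class `fedtte_colspec`.
#' @export
column_spec <- function(time_col, event_col, group_col = NULL,
                        covariate_cols = character(),
                        time_unit = c("days", "weeks", "months", "years")) {
  time_unit <- match.arg(time_unit)
  if (identical(time_col, event_col))
    config_error("time_col and event_col must name different columns")
  reserved <- c(time_col, event_col, group_col)
  clash <- intersect(covariate_cols, reserved)
  if (length(clash))
    config_error(sprintf("covariate column '%s' duplicates a time/event/group column",
                         clash[1]))
  structure(list(time_col = time_col, event_col = event_col,
                 group_col = group_col, covariate_cols = covariate_cols,
                 time_unit = time_unit),
            class = "fedtte_colspec")
}

coerce_events <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
  } else {
    x <- trimws(as.character(x))
    ok <- x %in% c("0", "1", "TRUE", "FALSE", "True", "False")
    bad <- which(!is.na(x) & x != "" & !ok)
    x <- ifelse(x %in% c("TRUE", "True"), "1",
                ifelse(x %in% c("FALSE", "False"), "0", x))
    x[x == ""] <- NA
    x <- suppressWarnings(as.numeric(x))
  }
  if (length(bad))
    data_error(sprintf(
      "event column contains values other than 0/1/TRUE/FALSE at rows: %s",
      toString(utils::head(bad, 10))))
  x
}

#' Construct a validated single-site survival dataset
#'
#' The in-memory unit every algorithm consumes: observed durations, event
#' indicators, optional group labels and an optional numeric covariate
#' matrix, all of equal length. Subjects with `time = 0` are retained.
#'
#' @param site_id Site identifier.
#' @param times Non-negative durations (canonical unit).
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @param groups Optional group labels (character/factor).
#' @param covariates Optional numeric matrix (subjects x p) with column names.
#' @param n_dropped Number of rows removed during validation (bookkeeping).
#' @return Object of class `fedtte_site`.
#' @export
site_dataset <- function(site_id, times, events, groups = NULL,
                         covariates = NULL, n_dropped = 0L) {
  times <- as.numeric(times)
  events <- coerce_events(events)
  n <- length(times)
  if (length(events) != n)
    data_error("times and events must have the same length")
  if (any(is.na(times)) || any(is.na(events)))
    data_error("times and events must not contain missing values")
  if (any(times < 0))
    data_error("negative durations are not allowed")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != n) data_error("groups must match the number of subjects")
    if (any(is.na(groups))) data_error("groups must not contain missing values")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      data_error("covariate matrix must have one row per subject")
    if (any(is.na(covariates)))
      data_error("covariate matrix must not contain missing values after validation")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  if (n == 0)
    data_error(sprintf("site '%s' has no usable rows", site_id))
  structure(list(site_id = site_id, times = times, events = events,
                 groups = groups, covariates = covariates,
                 n_dropped = as.integer(n_dropped)),
            class = "fedtte_site")
}

#' @export
print.fedtte_site <- function(x, ...) {
  cat(sprintf("Site '%s': %d subjects, %d events (%d rows dropped on read)\n",
              x$site_id, length(x$times), sum(x$events), x$n_dropped))
  if (!is.null(x$groups))
    cat("  groups:", toString(sort(unique(x$groups))), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", toString(colnames(x$covariates)), "\n")
  invisible(x)
}

#' Read one site's subject table from delimited text
#'
#' Rows with missing time, event or covariate values are dropped
#' (complete-case within site) and counted in `n_dropped`; times are
#' converted from `spec$time_unit` to the canonical unit.
#'
#' @param path File path (CSV by default).
#' @param spec A [column_spec()].
#' @param site_id Site identifier; defaults to the file name.
#' @param sep Field separator (`","` or `"\t"`).
#' @param canonical_unit Unit durations are converted into (study-wide).
#' @return A [site_dataset()].
#' @export
read_site_table <- function(path, spec, site_id = NULL, sep = ",",
                            canonical_unit = "days") {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (is.null(site_id))
    site_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(spec$time_col, spec$event_col, spec$group_col, spec$covariate_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    config_error(sprintf("required column '%s' not found in %s",
                         missing_cols[1], path))

  times <- suppressWarnings(as.numeric(df[[spec$time_col]]))
  events <- coerce_events(df[[spec$event_col]])
  cov <- NULL
  if (length(spec$covariate_cols)) {
    cov <- as.matrix(df[spec$covariate_cols])
    storage.mode(cov) <- "double"
  }
  keep <- !is.na(times) & !is.na(events)
  if (!is.null(cov)) keep <- keep & stats::complete.cases(cov)
  n_dropped <- sum(!keep)
  if (!any(keep))
    data_error(sprintf("no usable rows remain in %s after filtering", path))

  factor_to_canon <- .time_unit_days[[spec$time_unit]] /
    .time_unit_days[[canonical_unit]]
  site_dataset(
    site_id = site_id,
    times = times[keep] * factor_to_canon,
    events = events[keep],
    groups = if (!is.null(spec$group_col)) df[[spec$group_col]][keep],
    covariates = if (!is.null(cov)) cov[keep, , drop = FALSE],
    n_dropped = n_dropped)
}

#' Write a survival / cumulative-hazard step function to CSV
#'
#' Columns: `timeline`, `estimate`, `at_risk`, `events`, plus
#' `ci_lower`/`ci_upper` when a confidence interval is present.
#'
#' @param result A step-function result (see [kaplan_meier()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_step_function <- function(result, path) {
  if (length(result$timeline) == 0)
    data_error("step function has an empty timeline")
  df <- data.frame(timeline = result$timeline,
                   estimate = result$estimate,
                   at_risk = result$counts$n,
                   events = result$counts$d)
  if (!is.null(result$ci_lower)) {
    df$ci_lower <- result$ci_lower
    df$ci_upper <- result$ci_upper
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Read back a step function written by [write_step_function()]
#'
#' @param path CSV path.
#' @param kind `"survival"` or `"cumulative_hazard"` tag for the result.
#' @return A `fedtte_stepfun` object.
#' @export
read_step_function <- function(path, kind = "survival") {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  new_stepfun(
    timeline = df$timeline, estimate = df$estimate, kind = kind,
    counts = new_count_matrix(df$timeline, d = df$events, n = df$at_risk,
                              c = rep(0, nrow(df)), validate = FALSE),
    ci_lower = df$ci_lower, ci_upper = df$ci_upper)
}
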