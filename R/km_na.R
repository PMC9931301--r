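# Shared timelines, per-site count matrices, and the federated
# Kaplan-Meier and Nelson-Aalen estimators built from aggregated counts.
#
# Two timeline origins:
#  * union_of_event_times: points are the distinct observed event times;
#    counts at a point refer to that exact time (reproduces the centralized
#    estimators exactly).
#  * fixed_grid: a site-independent grid; observations are assigned to the
#    interval (t_{i-1}, t_i] (i.e. snapped up to the next grid point), so a
#    site's true event times are not disclosed. When the grid is at least
#    as fine as the time measurement unit, snapping is the identity and the
#    estimates are unchanged.

#' Timeline from the union of observed event times
#'
#' @param sites List of [site_dataset()] objects (or a single one).
#' @return A `fedtte_timeline` with origin `union_of_event_times`.
#' @export
timeline_union <- function(sites) {
  if (inherits(sites, "fedtte_site")) sites <- list(sites)
  ev <- unlist(lapply(sites, function(s) s$times[s$events == 1]))
  if (length(ev) == 0) data_error("no events observed; timeline would be empty")
  new_timeline(sort(unique(ev)), origin = "union_of_event_times")
}

#' Fixed, site-independent timeline grid
#'
#' Grid points `resolution, 2*resolution, ..., >= horizon`. Used in hybrid
#' mode so that the set of exchanged time points carries no information
#' about any site's event times.
#'
#' @param horizon Largest time that must be covered (study horizon).
#' @param resolution Grid step in canonical time units.
#' @return A `fedtte_timeline` with origin `fixed_grid`.
#' @export
timeline_grid <- function(horizon, resolution = 1) {
  if (resolution <= 0) config_error("grid resolution must be positive")
  if (horizon <= 0) config_error("study horizon must be positive")
  pts <- seq(resolution, by = resolution,
             length.out = ceiling(horizon / resolution))
  new_timeline(pts, origin = "fixed_grid", resolution = resolution)
}

new_timeline <- function(points, origin, resolution = NULL) {
  points <- as.numeric(points)
  if (length(points) == 0) data_error("timeline must be non-empty")
  if (any(diff(points) <= 0)) data_error("timeline must be strictly increasing")
  if (any(points < 0)) data_error("timeline points must be non-negative")
  structure(list(points = points, origin = origin, resolution = resolution),
            class = "fedtte_timeline")
}

# Snap times up to the covering grid point; identity on union timelines.
snap_times <- function(times, timeline) {
  if (timeline$origin != "fixed_grid") return(times)
  p <- timeline$points
  idx <- findInterval(times, p, left.open = TRUE) + 1L
  if (any(idx > length(p)))
    data_error("observed times exceed the fixed grid horizon")
  p[idx]
}

new_count_matrix <- function(timeline, d, n, c, group_label = NULL,
                             validate = TRUE) {
  if (inherits(timeline, "fedtte_timeline")) tl <- timeline
  else tl <- new_timeline(timeline, origin = "union_of_event_times")
  m <- length(tl$points)
  stopifnot(length(d) == m, length(n) == m, length(c) == m)
  if (validate) {
    if (any(d < 0) || any(c < 0) || any(n < 0))
      data_error("count matrix entries must be non-negative")
    if (any(d > n)) data_error("events cannot exceed the at-risk count")
    if (any(diff(n) > 0)) data_error("at-risk counts must be non-increasing")
  }
  structure(list(timeline = tl, d = as.numeric(d), n = as.numeric(n),
                 c = as.numeric(c), group_label = group_label),
            class = "fedtte_counts")
}

#' Per-time-point event / at-risk / censoring counts for one site
#'
#' For each timeline point `t_i`: `d_i` events, `n_i` subjects at risk and
#' `c_i` censorings. On a union timeline, `d_i` counts events at exactly
#' `t_i`, `n_i` counts subjects with time `>= t_i` (censored subjects tied
#' with an event time are in the risk set, the standard Kaplan-Meier
#' convention), and `c_i` counts censorings in `[t_i, t_{i+1})`. On a fixed
#' grid, observations are first snapped up to their covering grid point.
#'
#' @param data A [site_dataset()].
#' @param timeline A shared `fedtte_timeline`.
#' @param group Optional group label: restrict counting to that group.
#' @return A `fedtte_counts` object (the matrix a site shares).
#' @export
build_count_matrix <- function(data, timeline, group = NULL) {
  times <- data$times
  events <- data$events
  if (!is.null(group)) {
    if (is.null(data$groups))
      data_error("dataset has no group column")
    if (!group %in% data$groups)
      data_error(sprintf("unknown group label '%s' at site '%s'",
                         group, data$site_id))
    sel <- data$groups == group
    times <- times[sel]; events <- events[sel]
  }
  p <- timeline$points
  m <- length(p)
  times <- snap_times(times, timeline)
  if (timeline$origin != "fixed_grid" && any(times[events == 1] > p[m]))
    data_error("event times exceed the timeline; extend the timeline")

  # at risk: subjects with (snapped) time >= t_i
  n_at_risk <- length(times) - findInterval(p, sort(times), left.open = TRUE)
  ev_t <- times[events == 1]
  cn_t <- times[events == 0]
  d <- as.numeric(tabulate(match(ev_t, p), nbins = m))
  if (timeline$origin == "fixed_grid") {
    c_cnt <- as.numeric(tabulate(match(cn_t, p), nbins = m))
  } else {
    # censoring in [t_i, t_{i+1}); the last interval is unbounded
    j <- findInterval(cn_t, p)
    c_cnt <- as.numeric(tabulate(j[j >= 1], nbins = m))
  }
  new_count_matrix(timeline, d = d, n = n_at_risk, c = c_cnt,
                   group_label = group)
}

#' Aggregate site count matrices into the global count matrix
#'
#' Elementwise sums of `d`, `n` and `c` across sites, either as plain sums
#' (the aggregator sees each site's matrix) or through an additive
#' secret-sharing round (the aggregator only sees the total). Integer
#' counts reconstruct exactly in either mode.
#'
#' @param matrices List of `fedtte_counts` on identical timelines.
#' @param mode `"plain"` or `"secret_shared"` (requires >= 3 sites).
#' @param audit Optional audit log.
#' @param round Audit round index.
#' @return Global `fedtte_counts`.
#' @export
aggregate_counts <- function(matrices, mode = c("plain", "secret_shared"),
                             audit = NULL, round = 1L) {
  mode <- match.arg(mode)
  k <- length(matrices)
  if (k == 0) protocol_error("no count matrices to aggregate")
  tl <- matrices[[1]]$timeline
  for (mk in matrices)
    if (!isTRUE(all.equal(mk$timeline$points, tl$points)))
      protocol_error("count matrices do not share the same timeline")
  if (mode == "plain") {
    d <- Reduce(`+`, lapply(matrices, `[[`, "d"))
    n <- Reduce(`+`, lapply(matrices, `[[`, "n"))
    c_ <- Reduce(`+`, lapply(matrices, `[[`, "c"))
    for (i in seq_len(k))
      audit_record(audit, round, paste0("site", i), "aggregator",
                   "local_counts")
  } else {
    if (k < 3)
      protocol_error(sprintf(
        "secret-shared aggregation requires at least 3 sites (got %d)", k))
    ring <- ring_config(k, fixedpoint_scale = 1)  # integer counts: exact
    flat <- lapply(matrices, function(mk) c(mk$d, mk$n, mk$c))
    names(flat) <- paste0("site", seq_len(k))
    tot <- secure_sum(flat, ring, audit = audit, round = round,
                      label = "counts")
    m <- length(tl$points)
    d <- tot[seq_len(m)]; n <- tot[m + seq_len(m)]; c_ <- tot[2 * m + seq_len(m)]
  }
  new_count_matrix(tl, d = d, n = n, c = c_,
                   group_label = matrices[[1]]$group_label)
}

new_stepfun <- function(timeline, estimate, kind, counts,
                        ci_lower = NULL, ci_upper = NULL, dp = FALSE) {
  tlp <- if (inherits(timeline, "fedtte_timeline")) timeline$points else timeline
  structure(list(timeline = tlp, estimate = estimate, kind = kind,
                 counts = counts, ci_lower = ci_lower, ci_upper = ci_upper,
                 dp = dp),
            class = "fedtte_stepfun")
}

#' Kaplan-Meier survival function from a global count matrix
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}; points with `n_i = 0`
#' contribute a factor of 1. Operating on the aggregated counts of K sites
#' yields the federated estimator, which is algebraically identical to the
#' centralized estimator on pooled data.
#'
#' @param global_counts Aggregated `fedtte_counts`.
#' @param conf_int If `TRUE`, add Greenwood pointwise 95\% intervals
#'   (plain-scale normal approximation, clipped to `[0, 1]`).
#' @return A `fedtte_stepfun` of kind `"survival"`.
#' @export
kaplan_meier <- function(global_counts, conf_int = FALSE) {
  d <- global_counts$d; n <- global_counts$n
  frac <- ifelse(n > 0, d / n, 0)
  s <- cumprod(1 - frac)
  res <- new_stepfun(global_counts$timeline, s, "survival", global_counts)
  if (conf_int) {
    gw <- ifelse(n > 0 & n > d, d / (n * (n - d)), 0)
    se <- s * sqrt(cumsum(gw))
    res$ci_lower <- pmax(0, s - 1.96 * se)
    res$ci_upper <- pmin(1, s + 1.96 * se)
  }
  res
}

#' Nelson-Aalen cumulative hazard from a global count matrix
#'
#' \eqn{H(t) = \sum_{t_i \le t} d_i / n_i}; points with `n_i = 0` are
#' skipped.
#'
#' @param global_counts Aggregated `fedtte_counts`.
#' @return A `fedtte_stepfun` of kind `"cumulative_hazard"`.
#' @export
nelson_aalen <- function(global_counts) {
  d <- global_counts$d; n <- global_counts$n
  frac <- ifelse(n > 0, d / n, 0)
  new_stepfun(global_counts$timeline, cumsum(frac), "cumulative_hazard",
              global_counts)
}

#' Evaluate a step function at arbitrary times
#'
#' Right-continuous step evaluation: the estimate at the largest timeline
#' point `<= t`; before the first point the survival function is 1 and the
#' cumulative hazard 0.
#'
#' @param result A `fedtte_stepfun`.
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of estimates.
#' @export
eval_stepfun <- function(result, times) {
  idx <- findInterval(times, result$timeline)
  base <- if (result$kind == "survival") 1 else 0
  c(base, result$estimate)[idx + 1L]
}

#' @export
print.fedtte_stepfun <- function(x, ...) {
  cat(sprintf("%s step function%s: %d time points, range [%g, %g]\n",
              if (x$kind == "survival") "Survival" else "Cumulative hazard",
              if (isTRUE(x$dp)) " (differentially private)" else "",
              length(x$timeline), min(x$estimate), max(x$estimate)))
  invisible(x)
}

#' Plot survival / hazard step functions, optionally per group
#'
#' @param x A `fedtte_stepfun` or a named list of them (one per group).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_step_functions <- function(x, ...) {
  if (inherits(x, "fedtte_stepfun")) x <- list(x)
  kind <- x[[1]]$kind
  xmax <- max(unlist(lapply(x, function(s) max(s$timeline))))
  ymax <- if (kind == "survival") 1 else
    max(unlist(lapply(x, function(s) max(s$estimate))))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "time", ylab = if (kind == "survival") "S(t)" else "H(t)",
                 ...)
  cols <- seq_along(x)
  for (i in seq_along(x)) {
    s <- x[[i]]
    y0 <- if (kind == "survival") 1 else 0
    graphics::lines(stats::stepfun(s$timeline, c(y0, s$estimate)),
                    col = cols[i], do.points = FALSE)
  }
  if (!is.null(names(x)))
    graphics::legend("topright", legend = names(x), col = cols, lty = 1)
  invisible(x)
}
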