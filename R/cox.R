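# Federated Cox proportional hazards regression (Breslow ties).
#
# The partial likelihood depends on per-site data only through three
# risk-set sums per timeline point i,
#   s0_i = sum_{l in R_i} exp(b'z_l)
#   s1_i = sum_{l in R_i} z_l exp(b'z_l)
#   s2_i = sum_{l in R_i} z_l z_l' exp(b'z_l)
# plus the static aggregates d_i (events per point) and zbar_i (covariate
# sums over events). Sites therefore exchange only these sums each
# Newton-Raphson iteration; with additive secret sharing the aggregator
# sees only their totals. Since the sums are additive over sites, the
# federated fit is algebraically identical to the pooled fit in plain mode.

# Sum equal-length site vectors, either in the clear or secret-shared.
federated_sum <- function(vectors, mode, audit = NULL, round = NA_integer_,
                          label = "vector", fixedpoint_scale = 1e6) {
  k <- length(vectors)
  if (mode != "hybrid") {
    for (i in seq_len(k))
      audit_record(audit, round, paste0("site", i), "aggregator",
                   paste0("local_", label))
    return(Reduce(`+`, vectors))
  }
  if (k < 3)
    protocol_error(sprintf(
      "hybrid mode requires at least 3 sites (got %d)", k))
  ring <- ring_config(k, fixedpoint_scale = fixedpoint_scale)
  names(vectors) <- paste0("site", seq_len(k))
  secure_sum(vectors, ring, audit = audit, round = round, label = label)
}

check_covariates <- function(sites) {
  if (is.null(sites[[1]]$covariates))
    data_error("Cox regression needs at least one covariate column")
  cols <- colnames(sites[[1]]$covariates)
  for (s in sites) {
    if (is.null(s$covariates) ||
        !identical(colnames(s$covariates), cols))
      data_error(sprintf(
        "covariate columns at site '%s' do not match the other sites; harmonize the tables first",
        s$site_id))
  }
  cols
}

#' Federated z-score normalization of covariates
#'
#' Two aggregation rounds: (1) local means and sample counts give the
#' global mean \eqn{m = \sum_k m_k n_k / \sum_k n_k}; (2) local sums of
#' squared deviations from `m` give the global standard deviation with
#' denominator \eqn{(\sum_k n_k) - 1}. Each site then transforms its
#' covariates to `(X - m) / sd`. Identical, by construction, to the pooled
#' z-score with one degree of freedom removed.
#'
#' @param sites List of [site_dataset()] with matching covariate columns.
#' @param mode `"federated"` (plain sums) or `"hybrid"` (secret-shared,
#'   >= 3 sites).
#' @param audit Optional audit log.
#' @return `list(sites = normalized sites, state = list(mean, sd, n_total))`.
#' @export
federated_normalize <- function(sites, mode = c("federated", "hybrid"),
                                audit = NULL) {
  mode <- match.arg(mode)
  cols <- check_covariates(sites)
  p <- length(cols)
  # round 1: global mean
  r1 <- lapply(sites, function(s) {
    nk <- length(s$times)
    c(nk, colSums(s$covariates))
  })
  tot <- federated_sum(r1, mode, audit, round = 1L, label = "moments")
  n_total <- tot[1]
  m_fed <- tot[-1] / n_total
  # round 2: global sd
  r2 <- lapply(sites, function(s)
    colSums((s$covariates - matrix(m_fed, nrow(s$covariates), p,
                                   byrow = TRUE))^2))
  ss <- federated_sum(r2, mode, audit, round = 2L, label = "moments")
  sd_fed <- sqrt(ss / (n_total - 1))
  if (any(sd_fed < sqrt(.Machine$double.eps)))
    data_error(sprintf(
      "covariate '%s' is constant across the pooled data and cannot be normalized",
      cols[which(sd_fed < sqrt(.Machine$double.eps))[1]]))
  norm_sites <- lapply(sites, function(s) {
    s$covariates <- sweep(sweep(s$covariates, 2, m_fed, "-"), 2, sd_fed, "/")
    s
  })
  list(sites = norm_sites,
       state = list(mean = stats::setNames(m_fed, cols),
                    sd = stats::setNames(sd_fed, cols),
                    n_total = n_total))
}

#' Static Cox initialization aggregates
#'
#' Per timeline point: the global number of events `d_i` and the global
#' covariate sums `z_i` over subjects whose event falls at that point.
#' These are computed once, before iteration. Timeline points with no
#' events carry zero rows (padding; in hybrid mode this padding is what
#' hides each site's true event times).
#'
#' @param sites Normalized sites (see [federated_normalize()]).
#' @param timeline Shared `fedtte_timeline` (union of event times in plain
#'   mode, a fixed grid in hybrid mode).
#' @param mode `"federated"` or `"hybrid"`.
#' @param audit Optional audit log.
#' @return `list(timeline, d, z)` with `z` an m x p matrix.
#' @export
cox_init_aggregates <- function(sites, timeline,
                                mode = c("federated", "hybrid"),
                                audit = NULL) {
  mode <- match.arg(mode)
  pts <- timeline$points
  m <- length(pts)
  p <- ncol(sites[[1]]$covariates)
  locals <- lapply(sites, function(s) {
    ts <- snap_times(s$times, timeline)
    ev <- s$events == 1
    idx <- match(ts[ev], pts)
    if (anyNA(idx))
      data_error(sprintf("event times at site '%s' missing from the shared timeline",
                         s$site_id))
    d_k <- as.numeric(tabulate(idx, nbins = m))
    z_k <- matrix(0, m, p)
    if (any(ev)) {
      zs <- rowsum(s$covariates[ev, , drop = FALSE], group = idx)
      z_k[as.integer(rownames(zs)), ] <- zs
    }
    c(d_k, as.numeric(z_k))
  })
  if (sum(vapply(sites, function(s) sum(s$events), numeric(1))) == 0)
    data_error("no events in any site; the Cox model is not identifiable")
  tot <- federated_sum(locals, mode, audit, round = 3L, label = "init")
  list(timeline = timeline, d = tot[seq_len(m)],
       z = matrix(tot[-seq_len(m)], m, p,
                  dimnames = list(NULL, colnames(sites[[1]]$covariates))))
}

#' Per-site risk-set sums for one Newton-Raphson iteration
#'
#' Computes, at the current coefficient vector, the three sums
#' `s0`, `s1`, `s2` over the risk set \eqn{R_i = \{l : t_l \ge t_i\}} for
#' every timeline point. Runs in O(n p^2 + m p^2) via cumulative sums over
#' the time-sorted subjects.
#'
#' @param site Normalized [site_dataset()].
#' @param beta Current coefficient vector (normalized scale).
#' @param timeline Shared `fedtte_timeline`.
#' @return `list(s0, s1, s2)`: length-m vector, m x p and m x p^2 matrices.
#'   Entries are non-finite if `exp(beta'z)` overflowed (callers must
#'   detect this and shorten the step).
#' @export
cox_local_stats <- function(site, beta, timeline) {
  pts <- timeline$points
  m <- length(pts)
  ts <- snap_times(site$times, timeline)
  Z <- site$covariates
  p <- ncol(Z)
  ord <- order(ts)
  ys <- ts[ord]
  Zs <- Z[ord, , drop = FALSE]
  w <- exp(drop(Zs %*% beta))
  n <- length(ys)

  # prefix sums over subjects sorted by time; risk set = suffix
  k_before <- findInterval(pts, ys, left.open = TRUE)  # #{ys < t_i}
  pick <- k_before + 1L

  pw <- c(0, cumsum(w))
  s0 <- pw[n + 1L] - pw[pick]

  WZ <- Zs * w
  cs1 <- rbind(0, apply(WZ, 2, cumsum))
  s1 <- matrix(rep(cs1[n + 1L, ], each = m), m, p) -
    cs1[pick, , drop = FALSE]

  ZZ <- Zs[, rep(seq_len(p), times = p), drop = FALSE] *
    Zs[, rep(seq_len(p), each = p), drop = FALSE] * w
  cs2 <- rbind(0, apply(ZZ, 2, cumsum))
  s2 <- matrix(rep(cs2[n + 1L, ], each = m), m, p * p) -
    cs2[pick, , drop = FALSE]

  list(s0 = s0, s1 = s1, s2 = s2)
}

# Aggregated penalized log-likelihood, gradient and information at beta.
# `agg` holds global d (m) and z (m x p); s0/s1/s2 are global sums.
cox_objective <- function(beta, agg, s0, s1, s2, penalty, l1_ratio,
                          l1_smooth = 1e-8) {
  use <- agg$d > 0 & s0 > 0
  p <- length(beta)
  d <- agg$d[use]
  zbar <- agg$z[use, , drop = FALSE]
  s0u <- s0[use]
  s1u <- s1[use, , drop = FALSE]
  s2u <- s2[use, , drop = FALSE]

  ll <- sum(zbar %*% beta) - sum(d * log(s0u))
  mu <- s1u / s0u                       # m' x p
  grad <- colSums(zbar) - colSums(d * mu)
  info <- matrix(0, p, p)
  mmu <- array(0, dim = c(nrow(mu), p, p))
  for (r in seq_len(p)) for (q in seq_len(p))
    mmu[, r, q] <- mu[, r] * mu[, q]
  for (r in seq_len(p)) for (q in seq_len(p)) {
    col <- (q - 1) * p + r
    info[r, q] <- sum(d * (s2u[, col] / s0u - mmu[, r, q]))
  }

  # elastic net 0.5 * penalty * ((1 - a) |b|_2^2 + a |b|_1), L1 smoothed
  if (penalty > 0) {
    sq <- sqrt(beta^2 + l1_smooth)
    pen <- 0.5 * penalty * ((1 - l1_ratio) * sum(beta^2) +
                              l1_ratio * sum(sq))
    pen_g <- penalty * ((1 - l1_ratio) * beta +
                          0.5 * l1_ratio * beta / sq)
    pen_h <- penalty * ((1 - l1_ratio) +
                          0.5 * l1_ratio * l1_smooth / sq^3)
  } else {
    pen <- 0; pen_g <- numeric(p); pen_h <- numeric(p)
  }
  list(obj = ll - pen, loglik = ll, grad = grad - pen_g,
       info = info + diag(pen_h, p))
}

# One aggregation round of s0/s1/s2 at beta, flattened per site.
cox_round <- function(sites, beta, timeline, mode, audit, round) {
  m <- length(timeline$points)
  p <- length(beta)
  locals <- lapply(sites, function(s) {
    st <- cox_local_stats(s, beta, timeline)
    c(st$s0, as.numeric(st$s1), as.numeric(st$s2))
  })
  if (!all(vapply(locals, function(v) all(is.finite(v)), logical(1))))
    return(NULL)  # overflow: caller shortens the step
  tot <- federated_sum(locals, mode, audit, round = round, label = "riskset")
  list(s0 = tot[seq_len(m)],
       s1 = matrix(tot[m + seq_len(m * p)], m, p),
       s2 = matrix(tot[m + m * p + seq_len(m * p * p)], m, p * p))
}

#' Fit a federated Cox proportional hazards model
#'
#' Full pipeline: federated z-score normalization, static initialization
#' aggregates, then Newton-Raphson on the Breslow partial likelihood with
#' per-iteration exchange of risk-set sums, optionally through additive
#' secret sharing (`mode = "hybrid"`). An elastic-net penalty
#' \eqn{\frac{1}{2} p ((1-\alpha)\|\beta\|_2^2 + \alpha\|\beta\|_1)} is
#' supported; the L1 term is smoothed so the Newton loop stays valid.
#' Coefficients, standard errors and confidence intervals are
#' back-transformed to the original covariate scale.
#'
#' @param sites List of [site_dataset()] with covariates.
#' @param penalty Penalizer `p >= 0` (0 = unpenalized).
#' @param l1_ratio Elastic-net mixing `alpha` in `[0, 1]` (0 = ridge).
#' @param tol Convergence threshold on the max absolute coefficient change.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param mode `"federated"` (plain aggregation; timeline is the union of
#'   distinct event times, result identical to the pooled fit) or
#'   `"hybrid"` (secret-shared aggregation over a fixed site-independent
#'   grid; >= 3 sites).
#' @param timeline Optional explicit `fedtte_timeline`; defaults to the
#'   event-time union (federated) or a grid at `grid_resolution` covering
#'   the study horizon (hybrid).
#' @param grid_resolution Grid step for the default hybrid timeline, in
#'   canonical time units. Results equal the plain fit when no two
#'   observations share a grid interval that did not already share a time.
#' @param audit Optional audit log.
#' @return A `fedtte_cox` object: coefficient table (log-HR, SE, HR, 95\%
#'   CI, Wald p), iteration count, log-likelihood trace, penalty settings.
#' @export
fit_cox <- function(sites, penalty = 0, l1_ratio = 0, tol = 1e-7,
                    max_iter = 50, mode = c("federated", "hybrid"),
                    timeline = NULL, grid_resolution = 1, audit = NULL) {
  mode <- match.arg(mode)
  if (inherits(sites, "fedtte_site")) sites <- list(sites)
  k <- length(sites)
  if (mode == "hybrid" && k < 3)
    protocol_error(sprintf(
      "hybrid mode requires at least 3 sites (got %d)", k))
  if (penalty < 0 || l1_ratio < 0 || l1_ratio > 1)
    config_error("penalty must be >= 0 and l1_ratio in [0, 1]")

  norm <- federated_normalize(sites, mode = mode, audit = audit)
  nsites <- norm$sites
  cols <- names(norm$state$sd)
  p <- length(cols)

  if (is.null(timeline)) {
    timeline <- if (mode == "hybrid") {
      horizon <- max(vapply(nsites, function(s) max(s$times), numeric(1)))
      timeline_grid(horizon, grid_resolution)
    } else timeline_union(nsites)
  }
  agg <- cox_init_aggregates(nsites, timeline, mode = mode, audit = audit)

  beta <- numeric(p)
  round_id <- 4L
  stats0 <- cox_round(nsites, beta, timeline, mode, audit, round_id)
  if (is.null(stats0)) numeric_error("risk-set sums overflowed at beta = 0")
  cur <- cox_objective(beta, agg, stats0$s0, stats0$s1, stats0$s2,
                       penalty, l1_ratio)
  trace <- cur$obj
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    n_iter <- it
    delta <- tryCatch(solve(cur$info, cur$grad), error = function(e)
      numeric_error(paste0(
        "singular information matrix; consider penalty > 0 (", conditionMessage(e), ")")))
    step <- 1
    accepted <- FALSE
    for (h in 0:10) {
      cand <- beta + step * delta
      round_id <- round_id + 1L
      st <- cox_round(nsites, cand, timeline, mode, audit, round_id)
      if (!is.null(st)) {
        nxt <- cox_objective(cand, agg, st$s0, st$s1, st$s2,
                             penalty, l1_ratio)
        if (is.finite(nxt$obj) && nxt$obj >= cur$obj - 1e-9) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted)
      numeric_error("step-halving failed to improve the penalized likelihood")
    moved <- max(abs(cand - beta))
    beta <- cand
    cur <- nxt
    trace <- c(trace, cur$obj)
    if (moved < tol) { converged <- TRUE; break }
  }

  cov_std <- tryCatch(solve(cur$info), error = function(e)
    matrix(NA_real_, p, p))
  se_std <- sqrt(pmax(diag(cov_std), 0))
  sd_fed <- norm$state$sd
  beta_orig <- beta / sd_fed
  se_orig <- se_std / sd_fed
  zval <- beta_orig / se_orig
  coef_tab <- data.frame(
    covariate = cols,
    beta = beta_orig,
    se = se_orig,
    hazard_ratio = exp(beta_orig),
    ci_lower = beta_orig - 1.96 * se_orig,
    ci_upper = beta_orig + 1.96 * se_orig,
    p_value = 2 * stats::pnorm(-abs(zval)),
    row.names = NULL)

  structure(list(
    coefficients = coef_tab,
    beta_std = stats::setNames(beta, cols),
    se_std = stats::setNames(se_std, cols),
    normalization = norm$state,
    loglik = cur$loglik,
    trace = trace,
    n_iterations = n_iter,
    converged = converged,
    penalty = penalty, l1_ratio = l1_ratio,
    mode = mode,
    timeline = timeline,
    n_total = norm$state$n_total,
    n_events = sum(agg$d),
    n_sites = k), class = "fedtte_cox")
}

#' @export
print.fedtte_cox <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Federated Cox proportional hazards model (%s mode, %d site%s)\n",
    x$mode, x$n_sites, if (x$n_sites == 1) "" else "s"))
  cat(sprintf("  n = %d, events = %d; %d Newton-Raphson iterations%s\n",
              x$n_total, x$n_events, x$n_iterations,
              if (x$converged) "" else " (NOT converged)"))
  if (x$penalty > 0)
    cat(sprintf("  elastic-net penalty = %g, l1_ratio = %g\n",
                x$penalty, x$l1_ratio))
  tab <- x$coefficients
  out <- data.frame(
    `log HR` = round(tab$beta, digits),
    se = round(tab$se, digits),
    HR = round(tab$hazard_ratio, digits),
    `95% CI` = sprintf("[%.*f, %.*f]", digits, tab$ci_lower,
                       digits, tab$ci_upper),
    p = signif(tab$p_value, 3),
    row.names = tab$covariate, check.names = FALSE)
  print(out)
  invisible(x)
}

#' Write a Cox result as a coefficient CSV and a JSON summary
#'
#' @param result A `fedtte_cox` fit.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the coefficient table.
#' @export
write_cox_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(result$coefficients, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      coefficients = result$coefficients,
      loglik = result$loglik,
      n_iterations = result$n_iterations,
      converged = result$converged,
      penalty = result$penalty,
      l1_ratio = result$l1_ratio,
      mode = result$mode), json_path, auto_unbox = TRUE, digits = NA)
  invisible(result$coefficients)
}

#' Forest plot of log hazard ratios with their confidence intervals
#'
#' @param fits Named list of `fedtte_cox` fits to compare side by side.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_forest <- function(fits, ...) {
  if (inherits(fits, "fedtte_cox")) fits <- list(fit = fits)
  tabs <- lapply(fits, `[[`, "coefficients")
  covs <- tabs[[1]]$covariate
  nfit <- length(fits)
  ylim <- c(0.5, length(covs) + 0.5)
  xlim <- range(unlist(lapply(tabs, function(t) c(t$ci_lower, t$ci_upper))))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "log hazard ratio (95% CI)", ylab = "", ...)
  graphics::axis(2, at = seq_along(covs), labels = covs, las = 1)
  graphics::abline(v = 0, lty = 3)
  for (f in seq_len(nfit)) {
    off <- (f - (nfit + 1) / 2) * 0.15
    t <- tabs[[f]]
    y <- seq_along(covs) + off
    graphics::segments(t$ci_lower, y, t$ci_upper, y, col = f)
    graphics::points(t$beta, y, pch = 19, col = f)
  }
  if (!is.null(names(fits)))
    graphics::legend("topright", legend = names(fits), col = seq_len(nfit),
                     lty = 1, pch = 19)
  invisible(fits)
}
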