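# Round-based in-process federation runner. Three modes:
#   central   - sites are pooled and the estimator runs directly (oracle);
#   federated - sites exchange plain local aggregates with the aggregator;
#   hybrid    - every exchange is routed through an additive secret-sharing
#               round (>= 3 sites) and the shared timeline is a fixed grid,
#               so the aggregator learns only global sums.
# Every message is recorded in an audit log.

#' Configure a federated time-to-event study
#'
#' @param algorithm `"km"`, `"na"`, `"logrank"` or `"cox"`.
#' @param mode `"central"`, `"federated"` or `"hybrid"`.
#' @param dp Optional [dp_config()]; only valid for km/na/logrank (the
#'   Laplace mechanism is applied to the released counts, which the Cox
#'   model does not have).
#' @param grid_resolution Timeline grid step used in hybrid mode.
#' @param penalty,l1_ratio,tol,max_iter Cox settings (see [fit_cox()]).
#' @param conf_int Add Greenwood confidence intervals to km output.
#' @param seed Study-level seed; child seeds for splitting and DP noise
#'   are derived from it.
#' @return An object of class `fedtte_config`.
#' @export
study_config <- function(algorithm = c("km", "na", "logrank", "cox"),
                         mode = c("federated", "central", "hybrid"),
                         dp = NULL, grid_resolution = 1,
                         penalty = 0, l1_ratio = 0, tol = 1e-7,
                         max_iter = 50, conf_int = FALSE, seed = NULL) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (!is.null(dp) && algorithm == "cox")
    config_error("differential privacy is only available for km/na/logrank outputs")
  structure(list(algorithm = algorithm, mode = mode, dp = dp,
                 grid_resolution = grid_resolution, penalty = penalty,
                 l1_ratio = l1_ratio, tol = tol, max_iter = max_iter,
                 conf_int = conf_int, seed = seed),
            class = "fedtte_config")
}

pool_sites <- function(sites) {
  cov <- NULL
  if (!is.null(sites[[1]]$covariates))
    cov <- do.call(rbind, lapply(sites, `[[`, "covariates"))
  groups <- NULL
  if (!is.null(sites[[1]]$groups))
    groups <- unlist(lapply(sites, `[[`, "groups"))
  site_dataset("pooled",
               times = unlist(lapply(sites, `[[`, "times")),
               events = unlist(lapply(sites, `[[`, "events")),
               groups = groups, covariates = cov,
               n_dropped = sum(vapply(sites, `[[`, integer(1), "n_dropped")))
}

study_timeline <- function(sites, config) {
  if (config$mode == "hybrid") {
    horizon <- max(vapply(sites, function(s) max(s$times), numeric(1)))
    timeline_grid(horizon, config$grid_resolution)
  } else {
    timeline_union(sites)
  }
}

#' Run a federated time-to-event study
#'
#' Dispatches to the algorithm modules, routing every cross-site exchange
#' as plain messages (federated) or through a secret-sharing round
#' (hybrid). Central mode pools the data and runs the estimator directly.
#'
#' @param config A [study_config()].
#' @param sites List of [site_dataset()] objects.
#' @return `list(result = , audit = )`; the result type depends on the
#'   algorithm (step function, list of log-rank results, or Cox fit).
#' @export
run_study <- function(config, sites) {
  if (inherits(sites, "fedtte_site")) sites <- list(sites)
  k <- length(sites)
  if (config$mode == "hybrid" && k < 3)
    protocol_error(sprintf(
      "hybrid mode requires at least 3 participating sites (got %d)", k))
  audit <- new_audit_log()
  agg_mode <- if (config$mode == "hybrid") "secret_shared" else "plain"
  dp_cfg <- config$dp
  if (!is.null(dp_cfg) && is.null(dp_cfg$seed) && !is.null(config$seed))
    dp_cfg$seed <- config$seed + 1L

  result <- switch(config$algorithm,
    km = , na = {
      run_sites <- if (config$mode == "central") list(pool_sites(sites)) else sites
      tl <- study_timeline(run_sites, config)
      mats <- lapply(run_sites, build_count_matrix, timeline = tl)
      gc_ <- if (config$mode == "central") mats[[1]]
             else aggregate_counts(mats, mode = agg_mode, audit = audit)
      if (!is.null(dp_cfg)) gc_ <- dp_noise_counts(gc_, dp_cfg)
      res <- if (config$algorithm == "km")
        kaplan_meier(gc_, conf_int = config$conf_int)
      else nelson_aalen(gc_)
      res$dp <- !is.null(dp_cfg)
      res
    },
    logrank = {
      if (is.null(sites[[1]]$groups))
        config_error("log-rank requires a group column in the site data")
      run_sites <- if (config$mode == "central") list(pool_sites(sites)) else sites
      tl <- study_timeline(run_sites, config)
      labels <- sort(unique(unlist(lapply(run_sites, `[[`, "groups"))))
      per_group <- lapply(stats::setNames(labels, labels), function(lb) {
        mats <- lapply(run_sites, function(s) {
          if (lb %in% s$groups) build_count_matrix(s, tl, group = lb)
          else new_count_matrix(tl, d = numeric(length(tl$points)),
                                n = numeric(length(tl$points)),
                                c = numeric(length(tl$points)),
                                group_label = lb)
        })
        g <- if (config$mode == "central") mats[[1]]
             else aggregate_counts(mats, mode = agg_mode, audit = audit)
        if (!is.null(dp_cfg)) g <- dp_noise_counts(g, dp_cfg)
        g$group_label <- lb
        g
      })
      logrank_all_pairs(per_group)
    },
    cox = {
      run_sites <- if (config$mode == "central") list(pool_sites(sites)) else sites
      fit_cox(run_sites,
              penalty = config$penalty, l1_ratio = config$l1_ratio,
              tol = config$tol, max_iter = config$max_iter,
              mode = if (config$mode == "hybrid") "hybrid" else "federated",
              grid_resolution = config$grid_resolution,
              audit = audit)
    })
  list(result = result, audit = audit)
}

#' Randomly partition a pooled dataset into K site datasets
#'
#' Sizes differ by at most one subject; the union of the parts is exactly
#' the pooled dataset. Deterministic given `seed`.
#'
#' @param pooled A [site_dataset()].
#' @param k Number of sites.
#' @param seed Optional integer seed.
#' @return List of `k` [site_dataset()] objects.
#' @export
split_dataset <- function(pooled, k, seed = NULL) {
  n <- length(pooled$times)
  if (k < 1) config_error("k must be at least 1")
  if (k > n)
    config_error(sprintf("cannot split %d subjects into %d sites", n, k))
  with_seed(seed, {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    starts <- cumsum(c(1, sizes[-k]))
    lapply(seq_len(k), function(i) {
      idx <- perm[seq(starts[i], length.out = sizes[i])]
      site_dataset(
        site_id = paste0("site", i),
        times = pooled$times[idx],
        events = pooled$events[idx],
        groups = if (!is.null(pooled$groups)) pooled$groups[idx],
        covariates = if (!is.null(pooled$covariates))
          pooled$covariates[idx, , drop = FALSE])
    })
  })
}
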