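cox_cohort <- function(n = 400, seed = 1, k = 1) {
  spec <- simulation_spec(
    n_subjects = n, beta = c(x1 = 0.5, x2 = -0.4),
    covariates = c("normal", "binary"), k_sites = k, seed = seed)
  generate_survival_data(spec)
}

test_that("federated z-score normalization equals the pooled z-score", {
  pooled <- cox_cohort(n = 200, seed = 2)[[1]]
  # single site: ordinary z-score with ddof = 1
  one <- federated_normalize(list(pooled))
  expect_equal(one$state$mean, colMeans(pooled$covariates))
  expect_equal(one$state$sd, apply(pooled$covariates, 2, stats::sd))
  expect_equal(colMeans(one$sites[[1]]$covariates), c(x1 = 0, x2 = 0),
               tolerance = 1e-12)
  expect_equal(apply(one$sites[[1]]$covariates, 2, stats::sd),
               c(x1 = 1, x2 = 1))

  # split in halves: identical global moments (exact algebraic identity)
  halves <- split_dataset(pooled, 2, seed = 3)
  two <- federated_normalize(halves)
  expect_equal(two$state$mean, one$state$mean)
  expect_equal(two$state$sd, one$state$sd)

  const <- site_dataset("c", times = 1:4, events = c(1, 0, 1, 1),
                        covariates = cbind(flat = rep(2, 4)))
  expect_error(federated_normalize(list(const)), "flat",
               class = "fedtte_data_error")

  other <- pooled; colnames(other$covariates) <- c("x1", "zz")
  expect_error(federated_normalize(list(pooled, other)),
               class = "fedtte_data_error")
})

test_that("initialization aggregates match direct enumeration and splits", {
  one <- site_dataset("s", times = 3, events = 1,
                      covariates = cbind(x = 1.2))
  tl <- timeline_union(list(one))
  agg <- cox_init_aggregates(list(one), tl)
  expect_equal(agg$d, 1)
  expect_equal(unname(agg$z), matrix(1.2, 1, 1))

  pooled <- cox_cohort(n = 150, seed = 5)[[1]]
  tlp <- timeline_union(list(pooled))
  whole <- cox_init_aggregates(list(pooled), tlp)
  parts <- cox_init_aggregates(split_dataset(pooled, 4, seed = 6), tlp)
  expect_equal(parts$d, whole$d)
  expect_equal(parts$z, whole$z)
  expect_equal(sum(whole$d), sum(pooled$events))

  # grid timeline: points without events carry zero padding
  grid <- timeline_grid(max(pooled$times), 30)
  gagg <- cox_init_aggregates(list(pooled), grid)
  expect_true(any(gagg$d == 0))
  expect_equal(sum(gagg$d), sum(pooled$events))
  expect_true(all(gagg$z[gagg$d == 0, ] == 0))
})

test_that("risk-set sums match a brute-force oracle", {
  set.seed(9)
  s <- site_dataset("s", times = c(2, 5, 5, 8, 11),
                    events = c(1, 1, 0, 1, 1),
                    covariates = cbind(a = stats::rnorm(5),
                                       b = stats::rnorm(5)))
  tl <- timeline_union(list(s))
  for (beta in list(c(0, 0), c(0.4, -0.7))) {
    st <- cox_local_stats(s, beta, tl)
    for (i in seq_along(tl$points)) {
      risk <- which(s$times >= tl$points[i])
      w <- exp(drop(s$covariates[risk, , drop = FALSE] %*% beta))
      expect_equal(st$s0[i], sum(w))
      expect_equal(st$s1[i, ], colSums(s$covariates[risk, , drop = FALSE] * w))
      s2_direct <- t(s$covariates[risk, , drop = FALSE] * w) %*%
        s$covariates[risk, , drop = FALSE]
      expect_equal(matrix(st$s2[i, ], 2, 2), unname(s2_direct))
    }
    # nested risk sets: s0 non-increasing along the timeline
    expect_true(all(diff(st$s0) <= 1e-12))
  }
  # beta = 0 reduces to risk-set cardinalities
  st0 <- cox_local_stats(s, c(0, 0), tl)
  expect_equal(st0$s0, c(5, 4, 2, 1))
})

test_that("federated fit equals the centralized Breslow fit on any split", {
  skip_if_not_installed("survival")
  pooled <- cox_cohort(n = 400, seed = 11)[[1]]
  cph <- survival::coxph(
    survival::Surv(pooled$times, pooled$events) ~ pooled$covariates,
    ties = "breslow")
  for (k in c(1, 3, 5)) {
    sites <- if (k == 1) list(pooled) else split_dataset(pooled, k, seed = k)
    fit <- fit_cox(sites)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients$beta - unname(stats::coef(cph)))),
              1e-6)
    expect_lt(max(abs(fit$coefficients$se -
                        unname(sqrt(diag(stats::vcov(cph)))))), 1e-6)
  }
})

test_that("fit satisfies stationarity of an independent brute-force likelihood", {
  pooled <- cox_cohort(n = 120, seed = 21)[[1]]
  fit <- fit_cox(list(pooled))
  # gradient of the brute-force Breslow partial log-likelihood, original scale
  g <- num_gradient(function(b)
    breslow_loglik(pooled$times, pooled$events, pooled$covariates, b),
    fit$coefficients$beta)
  expect_lt(max(abs(g)), 1e-3)

  # penalized case: stationarity of ll - 0.5 p ((1-a)|b|^2 + a |b|_1)
  p <- 5; a <- 0.5
  fitp <- fit_cox(list(pooled), penalty = p, l1_ratio = a)
  # penalty acts on the standardized scale; check there
  norm <- federated_normalize(list(pooled))
  gp <- num_gradient(function(b)
    breslow_loglik(pooled$times, pooled$events,
                   norm$sites[[1]]$covariates, b) -
      0.5 * p * ((1 - a) * sum(b^2) + a * sum(abs(b))),
    fitp$beta_std)
  expect_lt(max(abs(gp)), 1e-3)
})

test_that("ridge penalty shrinks coefficients monotonically toward zero", {
  pooled <- cox_cohort(n = 250, seed = 31)[[1]]
  norms <- vapply(c(0, 1, 10, 100, 10000), function(p)
    sqrt(sum(fit_cox(list(pooled), penalty = p)$beta_std^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 0.1 * norms[1])
})

test_that("hybrid fit on a coarsened grid stays near the plain fit", {
  pooled <- cox_cohort(n = 300, seed = 41)[[1]]
  sites <- split_dataset(pooled, 3, seed = 42)
  plain <- fit_cox(sites)
  hybrid <- fit_cox(sites, mode = "hybrid", grid_resolution = 7)
  expect_lt(max(abs(hybrid$beta_std - plain$beta_std)), 0.01)
  expect_error(fit_cox(sites[1:2], mode = "hybrid"),
               class = "fedtte_protocol_error")
})

test_that("result invariants: CI brackets beta, HR positive", {
  fit <- fit_cox(cox_cohort(n = 150, seed = 51))
  tab <- fit$coefficients
  expect_true(all(tab$ci_lower < tab$beta & tab$beta < tab$ci_upper))
  expect_true(all(tab$hazard_ratio > 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(diff(fit$trace) >= -1e-9))  # accepted steps never decrease
})

test_that("degenerate inputs raise classed errors", {
  no_cov <- site_dataset("s", times = 1:4, events = c(1, 0, 1, 1))
  expect_error(fit_cox(list(no_cov)), class = "fedtte_data_error")
  no_event <- site_dataset("s", times = 1:4, events = rep(0, 4),
                           covariates = cbind(x = stats::rnorm(4)))
  expect_error(fit_cox(list(no_event)), class = "fedtte_data_error")
  expect_error(fit_cox(cox_cohort(150, 61), penalty = -1),
               class = "fedtte_config_error")
})
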