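test_that("count matrices match hand enumeration", {
  s <- tiny_site()  # times 1,2,2,3; events 1,1,0,1
  cm <- build_count_matrix(s, timeline_union(list(s)))
  expect_equal(cm$timeline$points, c(1, 2, 3))
  expect_equal(cm$d, c(1, 1, 1))
  expect_equal(cm$n, c(4, 3, 1))
  expect_equal(cm$c, c(0, 1, 0))
  expect_equal(sum(cm$d), sum(s$events))
  expect_equal(cm$n[1], length(s$times))

  # all censored: d identically zero on an externally supplied timeline
  cens <- site_dataset("c", times = c(1, 4), events = c(0, 0))
  cm2 <- build_count_matrix(cens, fedtte:::new_timeline(c(1, 4), "union_of_event_times"))
  expect_equal(cm2$d, c(0, 0))

  # single subject, event at t = 5
  one <- site_dataset("o", times = 5, events = 1)
  cm3 <- build_count_matrix(one, timeline_union(list(one)))
  expect_equal(cm3$d, 1)
  expect_equal(cm3$n, 1)

  # unknown group label
  expect_error(build_count_matrix(s, timeline_union(list(s)), group = "zz"),
               class = "fedtte_data_error")
})

test_that("Kaplan-Meier and Nelson-Aalen match hand-computed values", {
  tl <- fedtte:::new_timeline(c(1, 2, 3), "union_of_event_times")
  g <- fedtte:::new_count_matrix(tl, d = c(1, 1, 1), n = c(4, 3, 1),
                                 c = c(0, 1, 0))
  expect_equal(kaplan_meier(g)$estimate, c(0.75, 0.5, 0))

  g1 <- fedtte:::new_count_matrix(
    fedtte:::new_timeline(5, "union_of_event_times"), d = 1, n = 2, c = 0)
  expect_equal(kaplan_meier(g1)$estimate, 0.5)
  expect_equal(nelson_aalen(g1)$estimate, 0.5)

  g2 <- fedtte:::new_count_matrix(
    fedtte:::new_timeline(c(1, 2), "union_of_event_times"),
    d = c(1, 1), n = c(4, 2), c = c(1, 0))
  expect_equal(nelson_aalen(g2)$estimate, c(0.25, 0.75))

  # no events: S = 1 and H = 0 throughout
  g3 <- fedtte:::new_count_matrix(tl, d = c(0, 0, 0), n = c(4, 3, 1),
                                  c = c(1, 2, 1))
  expect_equal(kaplan_meier(g3)$estimate, rep(1, 3))
  expect_equal(nelson_aalen(g3)$estimate, rep(0, 3))
})

test_that("count aggregation sums sites and validates timelines", {
  tl <- fedtte:::new_timeline(c(1, 2), "union_of_event_times")
  mk <- function(d, n) fedtte:::new_count_matrix(tl, d = d, n = n,
                                                 c = c(0, 0))
  mats <- list(mk(c(1, 0), c(3, 2)), mk(c(0, 2), c(4, 2)),
               mk(c(1, 1), c(5, 3)))
  agg <- aggregate_counts(mats, "plain")
  expect_equal(agg$d, c(2, 3))
  expect_equal(agg$n, c(12, 7))

  expect_equal(aggregate_counts(mats[1], "plain")$d, mats[[1]]$d)

  other <- fedtte:::new_count_matrix(
    fedtte:::new_timeline(c(1, 3), "union_of_event_times"),
    d = c(1, 0), n = c(3, 2), c = c(0, 0))
  expect_error(aggregate_counts(list(mats[[1]], other), "plain"),
               class = "fedtte_protocol_error")
  expect_error(aggregate_counts(mats[1:2], "secret_shared"),
               class = "fedtte_protocol_error")
})

test_that("secret-shared aggregation equals plain sums on random counts", {
  set.seed(5)
  for (trial in 1:20) {
    m <- sample(3:12, 1)
    tl <- fedtte:::new_timeline(sort(sample(1:100, m)), "union_of_event_times")
    mats <- lapply(1:3, function(i) {
      n <- sort(sample(0:50, m), decreasing = TRUE)
      d <- pmin(rpois(m, 1), n)
      fedtte:::new_count_matrix(tl, d = d, n = n, c = rpois(m, 1))
    })
    plain <- aggregate_counts(mats, "plain")
    ss <- aggregate_counts(mats, "secret_shared")
    expect_identical(ss$d, plain$d)
    expect_identical(ss$n, plain$n)
    expect_identical(ss$c, plain$c)
  }
})

test_that("federated estimators equal the centralized oracle on any split", {
  skip_if_not_installed("survival")
  pooled <- make_benchmark_like("lung_like", seed = 3)
  sf <- survival::survfit(survival::Surv(pooled$times, pooled$events) ~ 1)
  ev <- sf$time[sf$n.event > 0]
  na_oracle <- cumsum(sf$n.event / sf$n.risk)[sf$n.event > 0]

  for (k in c(1, 3, 5, 10)) {
    sites <- split_dataset(pooled, k, seed = k)
    tl <- timeline_union(sites)
    g <- aggregate_counts(lapply(sites, build_count_matrix, timeline = tl),
                          "plain")
    km <- kaplan_meier(g)
    expect_equal(eval_stepfun(km, ev), sf$surv[sf$n.event > 0],
                 tolerance = 1e-12)
    na <- nelson_aalen(g)
    expect_equal(eval_stepfun(na, ev), na_oracle, tolerance = 1e-12)
    # estimator invariants
    expect_true(all(diff(km$estimate) <= 0))
    expect_true(all(km$estimate >= 0 & km$estimate <= 1))
    expect_true(all(diff(na$estimate) >= -1e-12))
  }
})

test_that("a fine fixed grid reproduces the union-timeline estimates", {
  pooled <- make_benchmark_like("veteran_like", seed = 9)
  sites <- split_dataset(pooled, 3, seed = 1)
  tlu <- timeline_union(sites)
  km_u <- kaplan_meier(aggregate_counts(
    lapply(sites, build_count_matrix, timeline = tlu), "plain"))
  # grid at the measurement resolution (1 day): snapping is the identity
  tlg <- timeline_grid(max(pooled$times), 1)
  km_g <- kaplan_meier(aggregate_counts(
    lapply(sites, build_count_matrix, timeline = tlg), "secret_shared"))
  expect_equal(eval_stepfun(km_g, tlu$points), km_u$estimate,
               tolerance = 1e-12)
})

test_that("step evaluation is right-continuous with S(0-) = 1", {
  tl <- fedtte:::new_timeline(c(2, 4), "union_of_event_times")
  g <- fedtte:::new_count_matrix(tl, d = c(1, 1), n = c(2, 1), c = c(0, 0))
  km <- kaplan_meier(g)
  expect_equal(eval_stepfun(km, c(0, 1.99, 2, 3.5, 4, 100)),
               c(1, 1, 0.5, 0.5, 0, 0))
})
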