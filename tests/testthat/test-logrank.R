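mk_counts <- function(pts, d, n, c_ = rep(0, length(d)), label = NULL) {
  fedtte:::new_count_matrix(
    fedtte:::new_timeline(pts, "union_of_event_times"),
    d = d, n = n, c = c_, group_label = label)
}

test_that("pairwise log-rank matches the hand-computed example", {
  a <- mk_counts(1, d = 2, n = 10, label = "A")
  b <- mk_counts(1, d = 0, n = 10, label = "B")
  r <- logrank_pair(a, b)
  expect_equal(r$expected[["A"]], 1)
  expect_equal(r$expected[["B"]], 1)
  expect_equal(r$statistic, 2)
  expect_equal(r$p_value, stats::pchisq(2, 1, lower.tail = FALSE))
})

test_that("identical groups give zero statistic and conservation holds", {
  a <- mk_counts(c(1, 3), d = c(1, 2), n = c(8, 5), label = "A")
  r0 <- logrank_pair(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  set.seed(21)
  for (trial in 1:25) {
    m <- sample(2:10, 1)
    pts <- sort(sample(1:50, m))
    nA <- sort(sample(1:40, m), decreasing = TRUE)
    nB <- sort(sample(1:40, m), decreasing = TRUE)
    a <- mk_counts(pts, pmin(rpois(m, 1), nA), nA, label = "A")
    b <- mk_counts(pts, pmin(rpois(m, 1), nB), nB, label = "B")
    r <- logrank_pair(a, b)
    # E_A + E_B = O_A + O_B exactly, and the statistic is label-symmetric
    expect_equal(sum(r$expected), sum(r$observed))
    rs <- logrank_pair(b, a)
    expect_equal(rs$statistic, r$statistic)
    expect_gte(r$statistic, 0)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("variance-weighted variant matches survdiff", {
  skip_if_not_installed("survival")
  pooled <- two_group_cohort(n = 250, effect = 0.5, seed = 8)
  tl <- timeline_union(list(pooled))
  labs <- sort(unique(pooled$groups))
  per <- lapply(stats::setNames(labs, labs), function(lb)
    build_count_matrix(pooled, tl, group = lb))
  r <- logrank_pair(per[[1]], per[[2]], variant = "variance")
  sd_ <- survival::survdiff(
    survival::Surv(pooled$times, pooled$events) ~ pooled$groups)
  expect_equal(r$statistic, sd_$chisq, tolerance = 1e-10)
})

test_that("federated pairwise statistic equals the pooled computation", {
  pooled <- two_group_cohort(n = 400, effect = 0.4, seed = 13)
  tl <- timeline_union(list(pooled))
  labs <- sort(unique(pooled$groups))
  pooled_counts <- lapply(stats::setNames(labs, labs), function(lb)
    build_count_matrix(pooled, tl, group = lb))
  r_pooled <- logrank_pair(pooled_counts[[1]], pooled_counts[[2]])

  for (k in c(3, 5)) {
    sites <- split_dataset(pooled, k, seed = k + 1)
    per <- lapply(stats::setNames(labs, labs), function(lb)
      aggregate_counts(lapply(sites, build_count_matrix,
                              timeline = tl, group = lb), "plain"))
    r_fed <- logrank_pair(per[[1]], per[[2]])
    expect_equal(r_fed$statistic, r_pooled$statistic)
    expect_equal(r_fed$observed, r_pooled$observed)
    expect_equal(r_fed$expected, r_pooled$expected)
  }
})

test_that("all-pairs enumeration is complete, sorted and guarded", {
  tl_pts <- c(1, 2)
  mk <- function(lb) mk_counts(tl_pts, d = c(1, 0), n = c(5, 3), label = lb)
  four <- stats::setNames(lapply(c("d", "b", "a", "c"), mk),
                          c("d", "b", "a", "c"))
  res <- logrank_all_pairs(four)
  expect_length(res, 6)
  expect_equal(res[[1]]$group_a, "a")
  expect_length(logrank_all_pairs(four[1:2]), 1)
  expect_error(logrank_all_pairs(four[1]), class = "fedtte_config_error")

  empty <- mk_counts(tl_pts, d = c(0, 0), n = c(0, 0), label = "empty")
  expect_error(logrank_pair(four[[1]], empty), class = "fedtte_data_error")
})

test_that("log-rank results serialize to table and JSON faithfully", {
  a <- mk_counts(c(1, 2), d = c(2, 1), n = c(10, 6), label = "a")
  b <- mk_counts(c(1, 2), d = c(0, 1), n = c(9, 7), label = "b")
  res <- logrank_all_pairs(list(a = a, b = b))
  tab <- logrank_table(res)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$statistic, res[[1]]$statistic)
  p <- tempfile(fileext = ".json")
  write_logrank_report(res, p)
  back <- jsonlite::read_json(p)
  expect_equal(back[[1]]$statistic, res[[1]]$statistic)
  expect_equal(back[[1]]$group_a, "a")
})

test_that("null rejection rate is near nominal for the primary statistic", {
  set.seed(31)
  alpha <- 0.05
  nrep <- 400
  rej <- 0
  for (r in 1:nrep) {
    pooled <- two_group_cohort(n = 120, effect = 0, seed = 31000 + r)
    tl <- timeline_union(list(pooled))
    labs <- sort(unique(pooled$groups))
    cg <- lapply(stats::setNames(labs, labs), function(lb)
      build_count_matrix(pooled, tl, group = lb))
    rej <- rej + (logrank_pair(cg[[1]], cg[[2]])$p_value < alpha)
  }
  rate <- rej / nrep
  # 99% binomial band around the nominal level
  expect_gt(rate, alpha - 2.58 * sqrt(alpha * (1 - alpha) / nrep))
  expect_lt(rate, alpha + 2.58 * sqrt(alpha * (1 - alpha) / nrep))
})
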