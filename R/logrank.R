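# Pairwise log-rank comparison of two groups from their aggregated count
# matrices. The primary statistic is the observed-vs-expected chi-square
#   X^2 = (O_A - E_A)^2 / E_A + (O_B - E_B)^2 / E_B,
# with E computed from the pooled risk sets on the shared timeline; the
# hypergeometric-variance-weighted form is available as an alternative
# (variant = "variance"), since the two differ numerically in unbalanced
# designs.

#' Pairwise log-rank test from per-group global count matrices
#'
#' @param counts_a,counts_b Aggregated `fedtte_counts` for the two groups,
#'   on the identical shared timeline.
#' @param variant `"chisq_oe"` (observed/expected form, the primary
#'   statistic) or `"variance"` (classic statistic
#'   \eqn{(O_A-E_A)^2/V} with the hypergeometric variance `V`).
#' @return A `fedtte_logrank` result: observed and expected event counts,
#'   the statistic and the upper-tail p-value from a chi-square with one
#'   degree of freedom.
#' @export
logrank_pair <- function(counts_a, counts_b,
                         variant = c("chisq_oe", "variance")) {
  variant <- match.arg(variant)
  if (!isTRUE(all.equal(counts_a$timeline$points, counts_b$timeline$points)))
    protocol_error("group count matrices do not share the same timeline")
  if (sum(counts_a$n) == 0 || sum(counts_b$n) == 0)
    data_error("a group has zero subjects at risk over the whole timeline")

  dA <- counts_a$d; nA <- counts_a$n
  dB <- counts_b$d; nB <- counts_b$n
  d <- dA + dB; n <- nA + nB
  use <- n > 0
  O_A <- sum(dA); O_B <- sum(dB)
  E_A <- sum(nA[use] * d[use] / n[use])
  E_B <- sum(nB[use] * d[use] / n[use])

  if (variant == "chisq_oe") {
    stat <- 0
    if (E_A > 0) stat <- stat + (O_A - E_A)^2 / E_A
    if (E_B > 0) stat <- stat + (O_B - E_B)^2 / E_B
  } else {
    v_use <- use & n > 1
    V <- sum(d[v_use] * (nA[v_use] / n[v_use]) * (nB[v_use] / n[v_use]) *
               (n[v_use] - d[v_use]) / (n[v_use] - 1))
    stat <- if (V > 0) (O_A - E_A)^2 / V else 0
  }
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(group_a = counts_a$group_label %||% "A",
                 group_b = counts_b$group_label %||% "B",
                 observed = c(A = O_A, B = O_B),
                 expected = c(A = E_A, B = E_B),
                 statistic = stat, p_value = p, variant = variant),
            class = "fedtte_logrank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All pairwise log-rank tests across groups
#'
#' One test per unordered pair of group labels, labels compared in
#' lexical order. P-values are raw (no multiplicity adjustment); adjust
#' downstream with [stats::p.adjust()] if several pairs are compared.
#'
#' @param per_group_counts Named list: group label -> aggregated
#'   `fedtte_counts`.
#' @param variant Passed to [logrank_pair()].
#' @return List of `fedtte_logrank` results.
#' @export
logrank_all_pairs <- function(per_group_counts,
                              variant = c("chisq_oe", "variance")) {
  variant <- match.arg(variant)
  labels <- sort(names(per_group_counts))
  if (length(labels) < 2)
    config_error("log-rank comparison needs at least 2 groups")
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  lapply(pairs, function(pr) {
    a <- per_group_counts[[pr[1]]]; b <- per_group_counts[[pr[2]]]
    a$group_label <- a$group_label %||% pr[1]
    b$group_label <- b$group_label %||% pr[2]
    logrank_pair(a, b, variant = variant)
  })
}

#' @export
print.fedtte_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test (%s): %s vs %s\n",
              x$variant, x$group_a, x$group_b))
  cat(sprintf("  O = (%.0f, %.0f), E = (%.3f, %.3f)\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  X^2 = %.4f, p = %.4g (chi-square, df = 1)\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Tabulate pairwise log-rank results
#'
#' @param results List of `fedtte_logrank` (from [logrank_all_pairs()]).
#' @return A data frame: pair, observed, expected, statistic, p.
#' @export
logrank_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(group_a = r$group_a, group_b = r$group_b,
               O_A = r$observed[["A"]], O_B = r$observed[["B"]],
               E_A = r$expected[["A"]], E_B = r$expected[["B"]],
               statistic = r$statistic, p_value = r$p_value)))
}

#' Write pairwise log-rank results as a JSON report
#'
#' @param results List of `fedtte_logrank` (from [logrank_all_pairs()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_logrank_report <- function(results, path) {
  jsonlite::write_json(lapply(results, function(r)
    list(group_a = r$group_a, group_b = r$group_b,
         observed = as.list(r$observed), expected = as.list(r$expected),
         statistic = r$statistic, p_value = r$p_value,
         variant = r$variant)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
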