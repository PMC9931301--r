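# Additive secret sharing over the ring Z_{2^64} with fixed-point encoding.
#
# R has no native 64-bit integer, so ring elements are stored as two 32-bit
# limbs (hi, lo) held in doubles; every limb operation stays below 2^53 and
# is therefore exact. Aggregation of K site vectors proceeds in five steps:
# each site splits its encoded vector into K random additive shares, keeps
# one, distributes K-1; each site sums the shares it holds; the aggregator
# adds the K masked sums, which reconstructs the global sum and nothing else.

TWO32 <- 2^32
TWO16 <- 2^16

#' Ring configuration for additive secret sharing
#'
#' Defines the fixed-point encoding used to place real-valued statistics in
#' the ring \eqn{\mathbb{Z}_{2^{64}}}. Real values are multiplied by
#' `fixedpoint_scale` and rounded, so reconstruction of a sum over K parties
#' is exact for integers and accurate to `K / fixedpoint_scale` for reals.
#'
#' @param n_parties Number of participating sites; the scheme requires at
#'   least 3 (with 2 parties each site could subtract its own share from the
#'   global sum and recover the other site's value).
#' @param fixedpoint_scale Power-of-ten scale for encoding reals (default
#'   `1e6`, i.e. six decimal digits are preserved).
#' @return An object of class `fedtte_ring`.
#' @export
ring_config <- function(n_parties, fixedpoint_scale = 1e6) {
  if (n_parties < 3)
    protocol_error(sprintf(
      "additive secret sharing requires at least 3 sites (got %d)", n_parties))
  if (fixedpoint_scale < 1)
    config_error("fixedpoint_scale must be >= 1")
  structure(
    list(modulus = 2^64, fixedpoint_scale = fixedpoint_scale,
         n_parties = as.integer(n_parties)),
    class = "fedtte_ring")
}

# -- limb arithmetic (internal) ----------------------------------------------

ring_vec <- function(hi, lo) list(hi = hi, lo = lo)

ring_zero <- function(n) ring_vec(numeric(n), numeric(n))

ring_add <- function(a, b) {
  lo <- a$lo + b$lo
  carry <- as.numeric(lo >= TWO32)
  lo <- lo - carry * TWO32
  hi <- (a$hi + b$hi + carry) %% TWO32
  ring_vec(hi, lo)
}

ring_neg <- function(a) {
  borrow <- as.numeric(a$lo != 0)
  lo <- ifelse(a$lo == 0, 0, TWO32 - a$lo)
  hi <- (TWO32 - a$hi - borrow) %% TWO32
  ring_vec(hi, lo)
}

ring_sub <- function(a, b) ring_add(a, ring_neg(b))

# Uniform ring elements; built from four 16-bit draws per element so the
# result is uniform over [0, 2^64) under R's RNG stream.
ring_uniform <- function(n) {
  draw16 <- function() floor(stats::runif(n) * TWO16)
  ring_vec(hi = draw16() * TWO16 + draw16(),
           lo = draw16() * TWO16 + draw16())
}

# Non-negative integer-valued double (< 2^53) -> limbs, and back.
ring_from_uint <- function(x) ring_vec(hi = x %/% TWO32, lo = x %% TWO32)
ring_to_uint   <- function(a) a$hi * TWO32 + a$lo

#' Encode real values into the secret-sharing ring
#'
#' Values are scaled by the ring's fixed-point scale, rounded, and mapped
#' into \eqn{[0, 2^{64})}; negative values wrap around (two's-complement
#' style). The admissible range keeps headroom so that a sum over all
#' parties can neither wrap past the sign boundary nor lose precision in
#' double arithmetic.
#'
#' @param values Numeric vector.
#' @param ring A [ring_config()].
#' @return A ring vector (opaque; see [ss_decode()]).
#' @export
ss_encode <- function(values, ring) {
  x <- round(values * ring$fixedpoint_scale)
  limit <- min(ring$modulus / (2 * ring$n_parties), 2^52 / ring$n_parties)
  bad <- which(!is.finite(x) | abs(x) >= limit)
  if (length(bad))
    range_error(sprintf(
      "value %g at position %d exceeds the encodable range (|value| * scale must stay below %g)",
      values[bad[1]], bad[1], limit / ring$fixedpoint_scale))
  pos <- ring_from_uint(abs(x))
  neg <- ring_neg(pos)
  sgn <- x < 0
  ring_vec(hi = ifelse(sgn, neg$hi, pos$hi),
           lo = ifelse(sgn, neg$lo, pos$lo))
}

#' Decode a ring vector back to reals
#'
#' Inverse of [ss_encode()]. Elements at or above \eqn{2^{63}} are read as
#' negative (wraparound convention).
#'
#' @param rv Ring vector.
#' @param ring A [ring_config()].
#' @return Numeric vector.
#' @export
ss_decode <- function(rv, ring) {
  negative <- rv$hi >= TWO32 / 2
  neg <- ring_neg(rv)
  mag <- ifelse(negative, ring_to_uint(neg), ring_to_uint(rv))
  sgn <- ifelse(negative, -1, 1)
  sgn * mag / ring$fixedpoint_scale
}

#' Split a secret into additive shares
#'
#' Produces one `ShareBundle` per recipient: `n - 1` payloads are uniform
#' random ring vectors and the last is the secret minus their sum, so the
#' modular sum of all `n` payloads reconstructs the secret while any strict
#' subset is distributed independently of it.
#'
#' @param secret Ring vector (from [ss_encode()]).
#' @param n Number of parties (>= 3).
#' @param sender Site identifier stamped on each bundle.
#' @param recipients Site identifiers of the `n` recipients.
#' @return List of `n` bundles, each `list(sender, recipient, payload)`.
#' @export
make_shares <- function(secret, n, sender = "site",
                        recipients = paste0("site", seq_len(n))) {
  if (n < 3)
    protocol_error(sprintf(
      "secret sharing requires at least 3 sites (got %d)", n))
  len <- length(secret$lo)
  shares <- vector("list", n)
  acc <- ring_zero(len)
  for (j in seq_len(n - 1)) {
    shares[[j]] <- ring_uniform(len)
    acc <- ring_add(acc, shares[[j]])
  }
  shares[[n]] <- ring_sub(secret, acc)
  lapply(seq_len(n), function(j)
    list(sender = sender, recipient = recipients[j], payload = shares[[j]]))
}

#' Sum the share payloads held by one site
#'
#' Step 3 of the aggregation round: a site adds up all payloads it received
#' (including the one it kept for itself). The result is a masked partial
#' sum that reveals nothing about any individual secret.
#'
#' @param received List of share bundles addressed to one site.
#' @return `list(site, payload)` with the modular sum.
#' @export
masked_local_sum <- function(received) {
  if (length(received) == 0)
    protocol_error("no share bundles received; cannot form a masked sum")
  lens <- vapply(received, function(b) length(b$payload$lo), integer(1))
  if (length(unique(lens)) != 1)
    protocol_error("share payload lengths differ across bundles")
  acc <- ring_zero(lens[1])
  for (b in received) acc <- ring_add(acc, b$payload)
  list(site = received[[1]]$recipient, payload = acc)
}

#' Reconstruct the global sum from all masked sums
#'
#' Step 5: the aggregator adds the masked sums of every party; the random
#' masks cancel and the modular total equals the sum of all original
#' secrets, which is then decoded to reals.
#'
#' @param masked List of masked sums, one per party.
#' @param ring A [ring_config()].
#' @return Numeric vector: the elementwise global sum.
#' @export
reconstruct_global <- function(masked, ring) {
  if (length(masked) != ring$n_parties)
    protocol_error(sprintf(
      "expected masked sums from %d parties, received %d%s",
      ring$n_parties, length(masked),
      if (length(masked) > 0) {
        present <- vapply(masked, function(m) as.character(m$site), character(1))
        expected <- paste0("site", seq_len(ring$n_parties))
        missing <- setdiff(expected, present)
        if (length(missing)) paste0(" (missing: ", toString(missing), ")") else ""
      } else ""))
  acc <- ring_zero(length(masked[[1]]$payload$lo))
  for (m in masked) acc <- ring_add(acc, m$payload)
  ss_decode(acc, ring)
}

#' Run one complete secret-shared aggregation round
#'
#' Simulates the five-step workflow in process for K site vectors: encode,
#' share, exchange, masked partial sums, reconstruction. Optionally records
#' every message in an audit log (see [new_audit_log()]).
#'
#' @param vectors List of K equal-length numeric vectors, one per site.
#' @param ring A [ring_config()] with `n_parties = K`.
#' @param audit Optional audit log.
#' @param round Round index recorded in the audit log.
#' @param label Message label recorded in the audit log.
#' @return Numeric vector: elementwise sum over sites.
#' @export
secure_sum <- function(vectors, ring, audit = NULL, round = NA_integer_,
                       label = "vector") {
  k <- length(vectors)
  if (k != ring$n_parties)
    protocol_error(sprintf("ring is configured for %d parties but %d vectors supplied",
                           ring$n_parties, k))
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1)
    protocol_error("site vectors must have equal length")
  site_ids <- names(vectors)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(k))

  # step 1-2: each site shares its secret; bundles routed to recipients
  inbox <- lapply(seq_len(k), function(j) list())
  for (i in seq_len(k)) {
    bundles <- make_shares(ss_encode(vectors[[i]], ring), k,
                           sender = site_ids[i], recipients = site_ids)
    for (j in seq_len(k)) {
      inbox[[j]] <- c(inbox[[j]], list(bundles[[j]]))
      if (i != j)
        audit_record(audit, round, site_ids[i], site_ids[j],
                     paste0("secret_share:", label))
    }
  }
  # step 3-4: masked partial sums go to the aggregator
  masked <- lapply(seq_len(k), function(j) {
    audit_record(audit, round, site_ids[j], "aggregator",
                 paste0("masked_sum:", label))
    ms <- masked_local_sum(inbox[[j]])
    ms$site <- site_ids[j]
    ms
  })
  # step 5: reconstruction + broadcast
  out <- reconstruct_global(masked, ring)
  for (j in seq_len(k))
    audit_record(audit, round, "aggregator", site_ids[j],
                 paste0("global_aggregate:", label))
  out
}
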