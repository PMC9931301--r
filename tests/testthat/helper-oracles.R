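# Independent oracles used across the suite. These deliberately do not
# share code with the package internals they check.

# -- base-2^16 big-integer adder: oracle for modular ring arithmetic ------
# a ring element is represented here as 4 limbs of 16 bits, least
# significant first; input/output as the package's (hi, lo) 32-bit pairs.
limbs16 <- function(hi, lo) {
  c(lo %% 65536, lo %/% 65536, hi %% 65536, hi %/% 65536)
}
unlimbs16 <- function(l) {
  list(hi = l[3] + l[4] * 65536, lo = l[1] + l[2] * 65536)
}
add_mod64_oracle <- function(a, b) {  # scalar (hi, lo) pairs
  la <- limbs16(a$hi, a$lo); lb <- limbs16(b$hi, b$lo)
  out <- numeric(4); carry <- 0
  for (i in 1:4) {
    s <- la[i] + lb[i] + carry
    out[i] <- s %% 65536
    carry <- s %/% 65536
  }
  unlimbs16(out)  # carry out of limb 4 is the mod-2^64 reduction
}

# -- brute-force Breslow partial log-likelihood (risk sets enumerated) ----
breslow_loglik <- function(times, events, Z, beta) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    ev <- which(times == t & events == 1)
    risk <- which(times >= t)
    eta <- drop(Z[risk, , drop = FALSE] %*% beta)
    ll <- ll + sum(Z[ev, , drop = FALSE] %*% beta) -
      length(ev) * log(sum(exp(eta)))
  }
  ll
}

# central finite-difference gradient
num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# -- tiny fixture -------------------------------------------------------
tiny_site <- function(site_id = "a") {
  site_dataset(site_id, times = c(1, 2, 2, 3), events = c(1, 1, 0, 1))
}

# pooled two-group synthetic cohort used by several tests
two_group_cohort <- function(n = 300, effect = 0, seed = 1) {
  spec <- simulation_spec(n_subjects = n, beta = numeric(0),
                          covariates = character(),
                          n_groups = 2, group_effect = effect,
                          seed = seed)
  generate_survival_data(spec)[[1]]
}
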