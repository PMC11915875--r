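# Independent oracles used across tests. These re-derive quantities from
# first principles (explicit likelihoods, closed forms, exhaustive
# enumeration) and never call the package functions they check.

# Efron partial log-likelihood for a single-covariate Cox model, written
# directly from its definition; maximized on a bounded interval.
efron_loglik <- function(b, time, event, x) {
  ll <- 0
  for (tau in sort(unique(time[event == 1]))) {
    D <- which(time == tau & event == 1)
    R <- which(time >= tau)
    sR <- sum(exp(b * x[R]))
    sD <- sum(exp(b * x[D]))
    d <- length(D)
    ll <- ll + sum(b * x[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}

brute_force_cox_beta <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) efron_loglik(b, time, event, x),
                  interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Direct two-term KL summation for the Jensen-Shannon divergence.
jsd_direct <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# Exact expected rarefied richness: E[S(d)] = sum_t 1 - C(N - n_t, d)/C(N, d)
expected_richness <- function(counts_vec, d) {
  N <- sum(counts_vec)
  sum(1 - exp(lchoose(N - counts_vec, d) - lchoose(N, d)))
}

# Exhaustive over-representation p-value: enumerate every possible query of
# the same size and count those with overlap at least as large.
ora_enumerate <- function(query, universe, set) {
  k_obs <- length(intersect(query, set))
  combos <- utils::combn(length(universe), length(query))
  hits <- apply(combos, 2L, function(idx)
    length(intersect(universe[idx], set)) >= k_obs)
  mean(hits)
}

# Small two-cohort metadata frame for direct calls into the Cox/selection
# machinery without running the full generator.
tiny_metadata <- function(n, cohort = "cohortA", seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("%s_s%03d", cohort, seq_len(n)),
             cohort = cohort,
             age = rnorm(n, 66, 10),
             sex = sample(c("male", "female"), n, TRUE),
             stage = sample(c("I/IIA", "IIB"), n, TRUE, prob = c(0.3, 0.7)),
             smoking = sample(c("never", "current", "former", "not_reported"),
                              n, TRUE),
             os_time = tm <- rexp(n, 0.05), os_event = ev <- rbinom(n, 1, 0.7),
             rfs_time = tm, rfs_event = ev)
}
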