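test_that("cox_fit is zero under an exposure-swap symmetric design", {
  # paired tied deaths: swapping exposure labels maps the data to itself
  f <- cox_fit(time = c(1, 1, 2, 2), event = c(1, 1, 1, 1),
               exposure = c(0, 1, 0, 1))
  expect_equal(f$beta, 0, tolerance = 1e-8)
  expect_equal(f$hr, 1, tolerance = 1e-8)
  expect_true(f$converged)
  expect_true(f$ci95[1] <= f$hr && f$hr <= f$ci95[2])
})

test_that("cox_fit matches brute-force partial-likelihood maximization", {
  # fixed 4-sample dataset with distinct event times
  time <- c(2, 5, 7, 11); event <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  f <- cox_fit(time, event, x)
  expect_equal(f$beta, brute_force_cox_beta(time, event, x), tolerance = 1e-4)

  # randomized property suite on datasets of <= 6 samples (ties included)
  set.seed(31)
  checked <- 0
  while (checked < 25) {
    n <- sample(4:6, 1)
    time <- sample(1:4, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    x <- rnorm(n)
    if (sum(event) < 2) next
    f <- cox_fit(time, event, x)
    if (!f$converged || abs(f$beta) > 6) next # skip near-degenerate draws
    expect_equal(f$beta, brute_force_cox_beta(time, event, x),
                 tolerance = 1e-3)
    checked <- checked + 1
  }
})

test_that("monotone-likelihood fits are flagged, not raised", {
  # every exposed sample fails before any unexposed one
  f <- cox_fit(time = c(1, 2, 3, 10, 11, 12), event = rep(1, 6),
               exposure = c(1, 1, 1, 0, 0, 0))
  expect_false(f$converged)
  expect_error(cox_fit(1:4, c(0, 0, 0, 0), c(1, 0, 1, 0)), "events")
  expect_error(cox_fit(1:4, c(1, 1, 0, 0), rep(1, 4)), "constant")
})

test_that("DerSimonian-Laird pooling matches the hand-worked example", {
  fits <- data.frame(beta = c(0.5, 0.1), se = c(0.2, 0.2))
  m <- meta_random_effects(fits)
  expect_equal(m$q_stat, 2.0, tolerance = 1e-12)
  expect_equal(m$tau2, 0.04, tolerance = 1e-12)
  expect_equal(m$beta_pooled, 0.3, tolerance = 1e-12)
  expect_equal(m$se_pooled, 0.2, tolerance = 1e-12)

  # identical studies: no heterogeneity, fixed-effect answer
  h <- meta_random_effects(data.frame(beta = c(0.4, 0.4), se = c(0.2, 0.2)))
  expect_equal(h$beta_pooled, 0.4)
  expect_equal(h$tau2, 0)
  expect_equal(h$q_stat, 0)
  expect_equal(h$p_het, 1)
  expect_equal(h$se_pooled, 0.2 / sqrt(2), tolerance = 1e-12)

  # single study passes through
  s <- meta_random_effects(data.frame(beta = 0.7, se = 0.3))
  expect_equal(s$beta_pooled, 0.7)
  expect_equal(s$se_pooled, 0.3)
  expect_error(meta_random_effects(list()), "no fits")
})

test_that("pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(41)
  for (k in c(2, 3, 5)) {
    beta <- rnorm(k, 0.3, 0.4)
    se <- runif(k, 0.1, 0.5)
    ours <- meta_random_effects(data.frame(beta = beta, se = se))
    rma <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(ours$beta_pooled, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(ours$se_pooled, rma$se, tolerance = 1e-8)
    expect_equal(ours$tau2, rma$tau2, tolerance = 1e-8)
    expect_equal(ours$q_stat, rma$QE, tolerance = 1e-8)
    expect_equal(ours$p_het, rma$QEp, tolerance = 1e-8)
  }
})

test_that("with no heterogeneity the pool reduces to inverse-variance weights", {
  beta <- c(0.2, 0.2, 0.2); se <- c(0.1, 0.3, 0.2)
  m <- meta_random_effects(data.frame(beta = beta, se = se))
  w <- 1 / se^2
  expect_equal(m$tau2, 0)
  expect_equal(m$beta_pooled, sum(w * beta) / sum(w))
  expect_equal(m$se_pooled, sqrt(1 / sum(w)))
})

test_that("BH q-values follow the step-up enumeration", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # direct step-up: q_j = min over k >= j of m * p_(k) / k
  set.seed(51)
  p <- runif(12)
  m <- length(p)
  o <- order(p)
  q_oracle <- numeric(m)
  for (j in seq_len(m))
    q_oracle[o[j]] <- min(1, min(m * p[o][j:m] / (j:m)))
  expect_equal(bh_fdr(p), q_oracle)
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})
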