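test_that("alpha indices match closed forms", {
  counts <- rbind(a = c(5L, 3L, 1L, 1L, 1L), # F1 = 3, F2 = 0
                  b = c(10L, 10L, 10L, 10L, 0L),
                  c = c(7L, 0L, 0L, 0L, 0L))
  colnames(counts) <- paste0("t", 1:5)
  al <- alpha_diversity(counts)
  expect_equal(al$chao1[1], 5 + 3 * 2 / (2 * 1)) # = 8
  expect_equal(al$shannon[2], log(4), tolerance = 1e-12)
  expect_equal(al$simpson[2], 0.75, tolerance = 1e-12)
  expect_equal(al$chao1[3], 1)
  expect_equal(al$shannon[3], 0)
  expect_equal(al$simpson[3], 0)
  expect_true(all(al$chao1 >= al$observed))
  expect_true(all(al$shannon <= log(al$observed) + 1e-12))
  expect_error(alpha_diversity(rbind(c(0L, 0L))), "all-zero")
})

test_that("chao1 agrees with vegan's estimator", {
  set.seed(2)
  counts <- matrix(rpois(6 * 40, 1.2), 6, 40)
  counts[rowSums(counts) == 0, 1] <- 1L
  ours <- alpha_diversity(counts)$chao1
  vg <- t(vegan::estimateR(counts))[, "S.chao1"]
  expect_equal(unname(ours), unname(vg), tolerance = 1e-8)
})

test_that("group tests behave at extreme separation and under degeneracy", {
  set.seed(4)
  a <- rnorm(20)
  alpha <- data.frame(sample_id = paste0("s", 1:40),
                      chao1 = c(a, a + 10),
                      shannon = c(a, a + 10), simpson = runif(40))
  g <- rep(c("A", "B"), each = 20)
  res <- alpha_group_tests(alpha, g)
  expect_lt(res$p[res$index == "chao1"], 1e-5)
  expect_equal(res$test[1], "wilcoxon")

  # three identical groups with fully tied values
  alpha3 <- data.frame(chao1 = rep(1, 30), shannon = rep(2, 30),
                       simpson = rep(0.5, 30))
  res3 <- alpha_group_tests(alpha3, rep(c("A", "B", "C"), 10))
  expect_equal(res3$statistic, rep(0, 3))
  expect_equal(res3$test[1], "kruskal-wallis")
  expect_error(alpha_group_tests(alpha, rep("A", 40)), "two groups")
})

test_that("jsd matches a direct KL summation oracle and its bounds", {
  x <- rbind(s1 = c(1, 0), s2 = c(0.5, 0.5))
  J <- jsd_matrix(x)
  expect_equal(J[1, 2], jsd_direct(c(1, 0), c(0.5, 0.5)), tolerance = 1e-12)
  # identical profiles and disjoint supports
  y <- rbind(a = c(3, 1, 0, 0), b = c(6, 2, 0, 0), c = c(0, 0, 1, 5))
  Jy <- jsd_matrix(y)
  expect_equal(Jy[1, 2], 0, tolerance = 1e-12)
  expect_equal(Jy[1, 3], log(2), tolerance = 1e-12)

  set.seed(6)
  z <- matrix(rexp(10 * 8), 10, 8)
  Jz <- jsd_matrix(z)
  expect_equal(Jz, t(Jz))
  expect_true(all(Jz >= 0 & Jz <= log(2) + 1e-12))
  expect_equal(unname(diag(Jz)), rep(0, 10))
  for (pair in list(c(1, 2), c(3, 7), c(4, 9)))
    expect_equal(Jz[pair[1], pair[2]],
                 jsd_direct(z[pair[1], ], z[pair[2], ]), tolerance = 1e-10)
  # sqrt(JSD) satisfies the triangle inequality
  S <- sqrt(Jz)
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(S[i, j], S[i, k] + S[k, j] + 1e-12)
})

test_that("permanova attains the permutation floor under perfect separation", {
  set.seed(10)
  base <- matrix(rexp(20 * 12), 20, 12)
  base[1:10, 1:6] <- base[1:10, 1:6] + 50 # two well-separated clusters
  d <- jsd_matrix(base)
  lab <- rep(c("x", "y"), each = 10)
  res <- permanova(d, lab, n_perm = 99, seed = 1)
  expect_equal(res$p, 1 / 100)
  expect_gt(res$f, 1)
  expect_error(permanova(d, rep("x", 20), n_perm = 99), "constant")
})

test_that("permanova pseudo-F matches vegan::adonis2 without covariates", {
  set.seed(12)
  m <- matrix(rexp(18 * 10), 18, 10)
  d <- jsd_matrix(m)
  v <- factor(rep(c("a", "b", "c"), 6))
  ours <- permanova(d, v, n_perm = 99, seed = 2)
  ad <- vegan::adonis2(as.dist(d) ~ v, permutations = 99)
  expect_equal(ours$f, ad$F[1], tolerance = 1e-8)
  expect_gte(ours$p, 1 / 100) # +1 correction lower bound
})

test_that("stratified permutations stay within strata", {
  # distances driven entirely by cohort; within-cohort shuffles of a
  # cohort-confounded variable cannot break the association structure, so
  # the stratified p stays near 1 for a variable constant within strata
  set.seed(13)
  m <- matrix(rexp(20 * 8), 20, 8)
  m[11:20, 1:4] <- m[11:20, 1:4] + 20
  d <- jsd_matrix(m)
  strata <- rep(c("A", "B"), each = 10)
  res <- permanova(d, strata, strata = strata, n_perm = 99, seed = 3)
  expect_equal(res$p, 1) # every stratified permutation reproduces F exactly
})

test_that("rarefaction matches the hypergeometric expectation", {
  counts <- rbind(s1 = c(50L, 50L))
  rc <- rarefaction_curves(counts, depths = c(1, 2, 100), n_draws = 400,
                           seed = 5)
  expect_equal(rc$richness[rc$depth == 1], 1)
  expect_equal(rc$richness[rc$depth == 100], 2) # full depth: observed richness
  e2 <- expected_richness(c(50, 50), 2) # = 1 + 50/99
  expect_equal(e2, 1 + 50 / 99, tolerance = 1e-12)
  expect_lt(abs(rc$richness[rc$depth == 2] - e2), 0.08)
  # monotone in depth
  counts2 <- rbind(s1 = c(30L, 5L, 2L, 1L, 0L, 12L))
  rc2 <- rarefaction_curves(counts2, depths = c(2, 5, 10, 25, 50),
                            n_draws = 200, seed = 6)
  expect_true(all(diff(rc2$richness) >= -0.05))
  expect_error(rarefaction_curves(counts2, depths = 51), "exceeds")
})
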