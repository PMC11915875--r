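test_that("filter retains boundary taxa and removes rare/low-abundance ones", {
  # 10 samples; taxon A carries count 2 in exactly one sample (prevalence
  # exactly 0.10) and clears the mean relative-abundance floor; taxon B has
  # a 1 everywhere (never reaches min_count); taxon C is all zero.
  counts <- cbind(A = c(2L, rep(0L, 9)),
                  B = rep(1L, 10),
                  C = rep(0L, 10),
                  filler = rep(1000L, 10))
  rownames(counts) <- paste0("s", 1:10)
  res <- filter_taxa(counts, filter_spec())
  expect_true("A" %in% colnames(res$counts))
  expect_false("B" %in% colnames(res$counts))
  expect_false("C" %in% colnames(res$counts))
  rep_b <- res$report[res$report$taxon == "B", ]
  expect_match(rep_b$reason, "prevalence")
  expect_match(res$report$reason[res$report$taxon == "C"], "prevalence")
})

test_that("filter is monotone in its thresholds", {
  set.seed(42)
  counts <- matrix(rpois(30 * 60, lambda = rexp(60, 1 / 3)), 30, 60,
                   byrow = TRUE)
  counts[1, ] <- counts[1, ] + 1L # no all-zero sample
  colnames(counts) <- paste0("t", 1:60)
  rownames(counts) <- paste0("s", 1:30)
  strict <- filter_taxa(counts, filter_spec(2, 0.3, 1e-3))$counts
  for (spec in list(filter_spec(1, 0.3, 1e-3), filter_spec(2, 0.1, 1e-3),
                    filter_spec(2, 0.3, 1e-6))) {
    relaxed <- filter_taxa(counts, spec)$counts
    expect_true(all(colnames(strict) %in% colnames(relaxed)))
  }
})

test_that("filter errors on empty input and when everything is removed", {
  expect_error(filter_taxa(matrix(numeric(0), 0, 0)), "empty")
  counts <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(filter_taxa(counts, filter_spec(min_count = 5)), "removed")
})

test_that("clr matches the hand-computed two-taxon example", {
  counts <- matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a", "b")))
  clr <- clr_transform(counts, pseudocount = 1)
  # x = (2, 4); geometric mean sqrt(8)
  expect_equal(clr[1, ], c(a = log(2) - log(sqrt(8)), b = log(4) - log(sqrt(8))),
               tolerance = 1e-12)
  expect_equal(unname(clr[1, ]), c(-0.3466, 0.3466), tolerance = 1e-4)
})

test_that("clr rows sum to zero and the transform is scale invariant", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(rpois(8 * 12, 20), 8, 12)
    clr <- clr_transform(counts, pseudocount = 1)
    expect_lt(max(abs(rowSums(clr))), 1e-8)
    # equal counts in a row -> all-zero clr row
    flat <- clr_transform(matrix(5, 1, 12), 1)
    expect_equal(unname(flat[1, ]), rep(0, 12))
    # scaling counts by c with the pseudocount scaled along is a no-op
    c_scale <- 3.7
    clr2 <- clr_transform(counts * c_scale, pseudocount = c_scale)
    expect_equal(clr2, clr, ignore_attr = TRUE, tolerance = 1e-10)
  }
  expect_error(clr_transform(matrix(1, 2, 2), pseudocount = 0), "pseudocount")
})

test_that("filter then clr commutes with sample reordering", {
  set.seed(11)
  counts <- matrix(rpois(10 * 20, 15), 10, 20,
                   dimnames = list(paste0("s", 1:10), paste0("t", 1:20)))
  ord <- sample(10)
  a <- clr_transform(filter_taxa(counts)$counts)[ord, ]
  b <- clr_transform(filter_taxa(counts[ord, ])$counts)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("batch centering removes a constant cohort shift and keeps row sums", {
  set.seed(3)
  clr0 <- clr_transform(matrix(rpois(20 * 15, 30), 20, 15))
  cohort <- rep(c("A", "B"), each = 10)
  # identity on a single cohort
  expect_equal(batch_center(clr0, rep("A", 20)), clr0, ignore_attr = TRUE)
  # a pure per-taxon shift on cohort B (row-sum preserving) is removed
  shift <- rnorm(15); shift <- shift - mean(shift)
  shifted <- clr0
  shifted[cohort == "B", ] <- sweep(shifted[cohort == "B", ], 2, -shift)
  centered <- batch_center(shifted, cohort)
  mA <- colMeans(centered[cohort == "A", ])
  mB <- colMeans(centered[cohort == "B", ])
  expect_equal(mA, mB, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(centered))), 1e-8)
  expect_error(batch_center(clr0, c("A", rep("B", 19))), "fewer than 2")
})
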