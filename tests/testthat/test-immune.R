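test_that("median binarization follows the documented tie rule", {
  expect_equal(binarize_by_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_by_median(c(1, 2, 2, 3)), c(0L, 0L, 0L, 1L))
  expect_error(binarize_by_median(rep(2, 5)), "constant")
})

test_that("logistic association reproduces the closed-form 2x2 odds ratio", {
  # table (20, 10; 10, 20): OR = 4, SE(log OR) = sqrt(1/20+1/10+1/10+1/20)
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  x <- c(rep(1, 30), rep(0, 30))
  ids <- paste0("s", 1:60)
  meta <- data.frame(sample_id = ids, cohort = "A")
  res <- logistic_assoc(matrix(y, dimnames = list(ids, "cell")),
                        setNames(x, ids), meta, covariates = character(0),
                        mode = "combined")
  expect_equal(res$or, 4, tolerance = 1e-6)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(res$ci_low, exp(log(4) - 1.96 * se), tolerance = 1e-4)
  expect_equal(res$ci_high, exp(log(4) + 1.96 * se), tolerance = 1e-4)
  expect_false(res$separated)
})

test_that("perfectly separated outcomes are flagged with unbounded CI", {
  y <- c(rep(0, 15), rep(1, 15))
  x <- sort(rnorm(30)) + c(rep(0, 15), rep(10, 15))
  ids <- paste0("s", 1:30)
  meta <- data.frame(sample_id = ids, cohort = "A")
  res <- logistic_assoc(matrix(y, dimnames = list(ids, "cell")),
                        setNames(x, ids), meta, covariates = character(0),
                        mode = "combined")
  expect_true(res$separated)
  expect_equal(res$ci_high, Inf)
})

test_that("meta mode pools per-cohort log odds ratios", {
  set.seed(91)
  n <- 120
  ids <- paste0("s", 1:n)
  meta <- data.frame(sample_id = ids,
                     cohort = rep(c("A", "B"), each = n / 2))
  score <- setNames(rnorm(n), ids)
  prob <- plogis(1.2 * score - 0.5) # below-half base rate keeps the median at 0
  cell <- runif(n) < prob # median-binarization keeps a 0/1 input intact
  res <- logistic_assoc(matrix(as.numeric(cell), dimnames = list(ids, "c1")),
                        score, meta, covariates = character(0), mode = "meta")
  expect_gt(res$or, 1)
  expect_false(is.na(res$p_het))
})

test_that("spearman correlations match hand ranks and are monotone-invariant", {
  res <- spearman_matrix(cbind(x = c(1, 2, 3)), cbind(y = c(3, 1, 2)))
  expect_equal(res$r, -0.5) # ranks (1,2,3) vs (3,1,2): sum d^2 = 6
  res2 <- spearman_matrix(cbind(x = 1:6), cbind(y = c(2, 4, 5, 7, 8, 12)))
  expect_equal(res2$r, 1)
  # strictly monotone transforms leave r unchanged; reversal negates it
  set.seed(95)
  x <- rnorm(25); y <- rnorm(25) + 0.5 * x
  r0 <- spearman_matrix(cbind(a = x), cbind(b = y))
  r1 <- spearman_matrix(cbind(a = exp(x)), cbind(b = y^3 + 5 * y))
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  r2 <- spearman_matrix(cbind(a = -x), cbind(b = y))
  expect_equal(r2$r, -r0$r, tolerance = 1e-12)
  # constant input is flagged
  rc <- spearman_matrix(cbind(a = rep(1, 5)), cbind(b = 1:5))
  expect_true(rc$flagged)
  expect_true(is.na(rc$r))
})

test_that("hypergeometric ORA matches closed forms and exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = universe[1:5], all = universe)
  res <- hypergeom_ora(universe[1:5], universe, sets)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1) # set = universe is never enriched
  # zero overlap: upper tail includes 0, so p = 1
  res0 <- hypergeom_ora(universe[6:7], universe, list(s = universe[1:5]))
  expect_equal(res0$p, 1)
  # exhaustive-enumeration oracle on a <= 15-gene universe
  set.seed(97)
  uni <- paste0("u", 1:12)
  for (i in 1:5) {
    q <- sample(uni, 4)
    s <- sample(uni, 5)
    p_pkg <- hypergeom_ora(q, uni, list(s = s))$p
    expect_equal(p_pkg, ora_enumerate(q, uni, s), tolerance = 1e-10)
  }
  expect_error(hypergeom_ora(character(0), universe, sets), "empty")
  expect_error(hypergeom_ora("zz", universe, sets), "outside")
})

test_that("GMT files round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2\tg4"), path)
  gs <- read_gmt(path)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, c("g2", "g4"))
})
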