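test_that("MRS raw scores are the hand-computed dot products", {
  clr <- rbind(s1 = c(sp1 = 1.0, sp2 = -0.5),
               s2 = c(sp1 = 0.2, sp2 = 0.8),
               s3 = c(sp1 = -1.2, sp2 = -0.3))
  meta <- data.frame(species = c("sp1", "sp2"), beta_pooled = c(0.5, -0.5))
  m <- build_mrs(clr, c("sp1", "sp2"), meta)
  expect_equal(unname(m$raw),
               c(0.5 * 1.0 - 0.5 * (-0.5),
                 0.5 * 0.2 - 0.5 * 0.8,
                 0.5 * (-1.2) - 0.5 * (-0.3)))
  expect_equal(mean(m$score), 0, tolerance = 1e-8)
  expect_equal(sd(m$score), 1, tolerance = 1e-8)
})

test_that("z-scoring makes the MRS invariant to weight rescaling", {
  set.seed(61)
  clr <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(paste0("s", 1:30), paste0("sp", 1:4)))
  meta <- data.frame(species = paste0("sp", 1:4),
                     beta_pooled = c(0.4, -0.2, 0.7, 0.1))
  m1 <- build_mrs(clr, paste0("sp", 1:4), meta)
  meta2 <- transform(meta, beta_pooled = beta_pooled * 2)
  m2 <- build_mrs(clr, paste0("sp", 1:4), meta2)
  expect_equal(m1$score, m2$score, tolerance = 1e-12)
  # single species: score is the z-scored clr column
  ms <- build_mrs(clr, "sp3", meta)
  expect_equal(unname(ms$score),
               as.numeric(scale(clr[, "sp3"])), tolerance = 1e-12)
  expect_error(build_mrs(clr, character(0), meta), "no selected")
})

test_that("median-split KM matches empirical survival without censoring", {
  score <- setNames(c(-2, -1.5, -1, 1, 1.5, 2), paste0("s", 1:6))
  time <- c(10, 12, 14, 1, 2, 3)
  km <- km_logrank(score, time, event = rep(1, 6))
  high <- km$curves[km$curves$group == "high", ]
  expect_equal(high$surv, c(2, 1, 0) / 3) # steps through (n-k)/n
  expect_equal(km$medians[["high"]], 2)
  expect_equal(km$medians[["low"]], 12)
  expect_true(all(diff(high$surv) <= 0))
})

test_that("log-rank statistic matches the hand hypergeometric computation", {
  # group A events at t = 1, 2 (n = 2); group B at t = 3, 4 (n = 2):
  # O - E = 1.1667, V = 0.4722 -> chi2 = 2.8824
  score <- setNames(c(2, 2, -1, -1), paste0("s", 1:4))
  km <- km_logrank(score, time = c(1, 2, 3, 4), event = rep(1, 4))
  expect_equal(km$logrank_chi2, 2.8824, tolerance = 1e-3)
  expect_lte(km$logrank_p, 1)
  # label swap leaves the two-group statistic unchanged
  km2 <- km_logrank(-score, time = c(1, 2, 3, 4), event = rep(1, 4))
  expect_equal(km2$logrank_chi2, km$logrank_chi2, tolerance = 1e-12)
  # identical groups: statistic 0
  score3 <- setNames(c(1, 1, -1, -1), paste0("s", 1:4))
  km3 <- km_logrank(score3, time = c(5, 9, 5, 9), event = rep(1, 4))
  expect_equal(km3$logrank_chi2, 0, tolerance = 1e-12)
})

test_that("all-censored groups yield a flagged undefined median", {
  score <- setNames(c(-1, -2, -3, 1, 2, 3), paste0("s", 1:6))
  km <- km_logrank(score, time = c(9, 9, 9, 1, 2, 3),
                   event = c(0, 0, 0, 1, 1, 1))
  expect_true(is.na(km$medians[["low"]]))
  expect_false(km$median_defined[["low"]])
  expect_true(km$median_defined[["high"]])
})

test_that("cox_mrs pools per-cohort fits and reports both HR scales", {
  cfg <- sim_config(n_per_cohort = c(60, 40), n_taxa = 15, n_causal = 2,
                    true_log_hr = 0.8, seed = 19)
  sim <- simulate_cohorts(cfg)
  clr <- clr_transform(sim$counts)
  assoc <- species_associations(clr, sim$metadata, "os")
  m <- build_mrs(clr, sim$truth$causal_taxa, assoc)
  cm <- cox_mrs(m, sim$metadata, "os")
  expect_s3_class(cm$pooled, "meta_estimate")
  expect_length(cm$per_cohort, 2)
  expect_gt(cm$hr_per_sd, 1) # true effects load positively on the score
  expect_equal(cm$hr_per_raw_unit, exp(log(cm$hr_per_sd) / m$scale),
               tolerance = 1e-12)
  # rescaling all weights leaves the z-scored HR unchanged
  assoc2 <- assoc; assoc2$beta_pooled <- assoc2$beta_pooled * 3
  m2 <- build_mrs(clr, sim$truth$causal_taxa, assoc2)
  cm2 <- cox_mrs(m2, sim$metadata, "os")
  expect_equal(cm2$hr_per_sd, cm$hr_per_sd, tolerance = 1e-8)
})

test_that("stratified rerun reduces to the unstratified fit for one stratum", {
  cfg <- sim_config(n_per_cohort = c(50, 30), n_taxa = 12, n_causal = 1,
                    true_log_hr = 0.8, seed = 23)
  sim <- simulate_cohorts(cfg)
  clr <- clr_transform(sim$counts)
  assoc <- species_associations(clr, sim$metadata, "os")
  m <- build_mrs(clr, sim$truth$causal_taxa, assoc)
  meta <- sim$metadata
  meta$one <- "all"
  tab <- stratified_rerun(m, meta, "os", strata_variable = "one")
  expect_equal(nrow(tab), 1)
  direct <- cox_fit(meta$os_time, meta$os_event, m$score,
                    build_covariates(meta))
  expect_equal(tab$hr, direct$hr, tolerance = 1e-10)
  # per-stage strata produce one row per usable level
  tab2 <- stratified_rerun(m, meta, "os", strata_variable = "stage")
  expect_true(all(tab2$stratum %in% unique(meta$stage)))
  expect_true(all(tab2$events >= 2))
  # a stratum with too few events is skipped with a warning
  meta$tiny <- ifelse(seq_len(nrow(meta)) <= 3, "rare", "common")
  meta$os_event[meta$tiny == "rare"] <- 0
  expect_warning(stratified_rerun(m, meta, "os", strata_variable = "tiny"),
                 "skipped")
})
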