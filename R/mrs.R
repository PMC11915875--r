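#' Build a Microbial Risk Score from selected species
#'
#' The raw score of sample `s` is the weighted sum
#' `sum_k beta_pooled_k * clr[s, k]` over the selected species, with weights
#' the pooled log-hazard-ratios from the meta-analysis; the score is then
#' z-scored across all samples of the combined cohorts. Z-scoring makes the
#' score invariant to rescaling all weights by a positive constant.
#'
#' @param clr pooled samples x species clr matrix.
#' @param selection a `selection_result` from [stability_select()] (or a
#'   character vector of species to use directly).
#' @param meta data.frame with columns `species` and `beta_pooled` (e.g.
#'   the association table of [species_associations()]).
#' @param outcome_tag label carried along, e.g. `"Mortality"` or
#'   `"Relapse"`.
#' @return object of class `mrs_vector`: `score` (named, z-scored), `raw`,
#'   `weights` (named per selected species), `center`, `scale`,
#'   `outcome_tag`.
#' @export
build_mrs <- function(clr, selection, meta, outcome_tag = "Mortality") {
  species <- if (is.character(selection)) selection
             else selection$table$species[selection$table$selected]
  if (length(species) == 0L) stop2("no selected species; cannot build an MRS")
  missing_clr <- setdiff(species, colnames(clr))
  if (length(missing_clr))
    stop2("selected species absent from clr matrix: ",
          paste(head(missing_clr, 5), collapse = ", "))
  w <- meta$beta_pooled[match(species, meta$species)]
  if (anyNA(w)) stop2("missing pooled estimates for some selected species")
  names(w) <- species
  raw <- drop(clr[, species, drop = FALSE] %*% w)
  ctr <- mean(raw); scl <- sd(raw)
  if (scl == 0) stop2("risk score is constant across samples")
  structure(list(score = (raw - ctr) / scl, raw = raw, weights = w,
                 center = ctr, scale = scl, outcome_tag = outcome_tag),
            class = "mrs_vector")
}

#' @export
print.mrs_vector <- function(x, ...) {
  cat(sprintf("MRS (%s): %d samples, %d species; raw center %.3f, scale %.3f\n",
              x$outcome_tag, length(x$score), length(x$weights),
              x$center, x$scale))
  invisible(x)
}

#' Cox models of survival on the Microbial Risk Score
#'
#' Fits covariate-adjusted Cox models of the outcome on the z-scored MRS:
#' per cohort with DerSimonian-Laird pooling (the primary report), and as a
#' single combined-cohort model. The z-scored fit is the HR per 1 SD of the
#' raw score; the HR per raw unit (`exp(beta/scale)`) is reported alongside.
#'
#' @param mrs an `mrs_vector` from [build_mrs()] (sample names must match
#'   `metadata$sample_id`).
#' @param metadata data.frame with `sample_id`, `cohort`, outcome columns
#'   and covariates.
#' @param outcome `"os"` or `"rfs"`.
#' @param covariates covariate names for [build_covariates()].
#' @param per_cohort fit per cohort and pool (default TRUE when >1 cohort).
#' @param ties Cox tie handling.
#' @return list of class `mrs_cox`: `pooled` (`meta_estimate` or NULL),
#'   `per_cohort` (named list of `cox_fit`), `combined` (`cox_fit`),
#'   `hr_per_sd`, `hr_per_raw_unit`.
#' @export
cox_mrs <- function(mrs, metadata, outcome = c("os", "rfs"),
                    covariates = c("age", "sex", "stage", "smoking"),
                    per_cohort = TRUE, ties = "efron") {
  outcome <- match.arg(outcome)
  score <- mrs$score
  meta <- metadata[match(names(score), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop2("metadata is missing scored samples")
  time <- meta[[paste0(outcome, "_time")]]
  event <- meta[[paste0(outcome, "_event")]]
  Z <- if (length(covariates)) build_covariates(meta, covariates) else NULL
  combined <- cox_fit(time, event, score, Z, ties = ties)
  fits <- NULL; pooled <- NULL
  if (per_cohort && length(unique(meta$cohort)) > 1L) {
    fits <- lapply(split(seq_along(score), as.character(meta$cohort)), function(idx) {
      m <- meta[idx, , drop = FALSE]
      Zi <- if (length(covariates)) build_covariates(m, covariates) else NULL
      cox_fit(time[idx], event[idx], score[idx], Zi, ties = ties)
    })
    pooled <- meta_random_effects(fits)
  }
  beta_sd <- if (!is.null(pooled)) pooled$beta_pooled else combined$beta
  structure(list(pooled = pooled, per_cohort = fits, combined = combined,
                 outcome = outcome, hr_per_sd = exp(beta_sd),
                 hr_per_raw_unit = exp(beta_sd / mrs$scale)),
            class = "mrs_cox")
}

#' @export
print.mrs_cox <- function(x, ...) {
  cat(sprintf("MRS Cox model (%s): HR per SD = %.3f\n", toupper(x$outcome),
              x$hr_per_sd))
  if (!is.null(x$pooled)) { cat("Pooled: "); print(x$pooled) }
  cat("Combined-cohort fit: "); print(x$combined)
  invisible(x)
}

#' Median-split Kaplan-Meier curves and log-rank test for an MRS
#'
#' Samples with score above the median form the high-risk group (ties go to
#' low risk); product-limit survival curves are estimated per group, the
#' two-group log-rank test and the likelihood-ratio test of the
#' corresponding two-group Cox model are computed, and median survival is
#' the earliest time at which the estimated survival drops to 0.5 or below
#' (undefined, with a flag, when a group never reaches it).
#'
#' @param mrs an `mrs_vector` (or plain named numeric score vector).
#' @param time,event outcome vectors aligned to the scores.
#' @return object of class `km_result`: `curves` (data.frame time, n.risk,
#'   n.event, surv per group), `logrank_chi2`, `logrank_p`, `lrt_p`,
#'   `medians` (per group, NA when undefined), `groups`.
#' @export
km_logrank <- function(mrs, time, event) {
  score <- if (inherits(mrs, "mrs_vector")) mrs$score else mrs
  n <- length(score)
  if (length(time) != n || length(event) != n)
    stop2("time/event lengths do not match scores")
  if (sum(event) < 1) stop2("need at least one event")
  group <- factor(ifelse(score > median(score), "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(group)) < 2L) stop2("median split produced a single group")
  y <- survival::Surv(time, event)
  sf <- survival::survfit(y ~ group)
  curves <- data.frame(time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       group = rep(sub("group=", "", names(sf$strata)),
                                   sf$strata))
  sdf <- survival::survdiff(y ~ group)
  chi2 <- sdf$chisq
  logrank_p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  ## the LRT remains defined when the group coefficient diverges (perfect
  ## separation); silence coxph's iteration warnings for those fixtures
  cox <- suppressWarnings(survival::coxph(y ~ group, ties = "efron"))
  lrt_p <- pchisq(2 * (cox$loglik[2] - cox$loglik[1]), df = 1L,
                  lower.tail = FALSE)
  medians <- vapply(split(curves, curves$group), function(cc) {
    i <- which(cc$surv <= 0.5)
    if (length(i)) min(cc$time[i]) else NA_real_
  }, 0)
  structure(list(curves = curves, logrank_chi2 = chi2,
                 logrank_p = logrank_p, lrt_p = lrt_p,
                 medians = medians,
                 median_defined = !is.na(medians), groups = group),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Median-split KM: log-rank chi2 = %.3f (p = %.3g), Cox LRT p = %.3g\n",
              x$logrank_chi2, x$logrank_p, x$lrt_p))
  med <- ifelse(is.na(x$medians), "not reached", sprintf("%.1f", x$medians))
  cat(sprintf("  median survival: low = %s, high = %s (months)\n",
              med["low"], med["high"]))
  invisible(x)
}

#' Re-run the MRS Cox model within strata of a clinical variable
#'
#' Fits the covariate-adjusted combined-cohort MRS Cox model separately in
#' each level of a stratifying variable (the variable itself is dropped
#' from the adjustment set). Levels with fewer than `min_events` events are
#' skipped with a warning.
#'
#' @param mrs an `mrs_vector`.
#' @param metadata as in [cox_mrs()].
#' @param outcome `"os"` or `"rfs"`.
#' @param strata_variable metadata column to stratify on.
#' @param covariates adjustment covariates (the stratifying one is removed).
#' @param min_events minimum events per stratum (default 2).
#' @return data.frame: stratum, n, events, hr, ci_low, ci_high, p.
#' @export
stratified_rerun <- function(mrs, metadata, outcome = c("os", "rfs"),
                             strata_variable,
                             covariates = c("age", "sex", "stage", "smoking"),
                             min_events = 2) {
  outcome <- match.arg(outcome)
  covariates <- setdiff(covariates, strata_variable)
  score <- mrs$score
  meta <- metadata[match(names(score), metadata$sample_id), , drop = FALSE]
  strata <- as.character(meta[[strata_variable]])
  if (is.null(meta[[strata_variable]]))
    stop2("metadata lacks strata column '", strata_variable, "'")
  rows <- list()
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    ev <- sum(meta[[paste0(outcome, "_event")]][idx])
    if (length(idx) < 4L || ev < min_events) {
      warning("stratum '", lev, "' skipped (", length(idx), " samples, ",
              ev, " events)", call. = FALSE)
      next
    }
    m <- meta[idx, , drop = FALSE]
    Z <- if (length(covariates)) build_covariates(m, covariates) else NULL
    f <- cox_fit(m[[paste0(outcome, "_time")]], m[[paste0(outcome, "_event")]],
                 score[idx], Z)
    rows[[lev]] <- data.frame(stratum = lev, n = length(idx), events = ev,
                              hr = f$hr, ci_low = f$ci95[1],
                              ci_high = f$ci95[2], p = f$p,
                              converged = f$converged)
  }
  if (length(rows) == 0L) stop2("no stratum had enough events")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
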