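## --- low-level Cox engine -------------------------------------------------
## Thin wrapper around survival::coxph.fit used everywhere a per-species fit
## is needed; the exposure is always column 1 of x. Returns c(beta, se) with
## NA when the fit is unusable, plus a convergence flag. Monotone-likelihood
## fits (the partial likelihood drifts to +/- infinity, e.g. when every
## exposed sample fails first) are detected by an effect-size guard and
## flagged rather than raised.
cox_engine <- function(x, y, ties = "efron", max_abs_beta = 10) {
  n <- nrow(x)
  fit <- tryCatch(
    suppressWarnings( # degenerate fits are detected below, not warned about
      survival::coxph.fit(x, y, strata = NULL, offset = rep(0, n),
                          init = rep(0, ncol(x)),
                          control = survival::coxph.control(),
                          weights = rep(1, n), method = ties, rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$coefficients) ||
      any(!is.finite(fit$coefficients)) || any(!is.finite(diag(fit$var))) ||
      any(diag(fit$var) <= 0))
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
  beta <- fit$coefficients[1L]
  se <- sqrt(fit$var[1L, 1L])
  ## coxph.fit carries no explicit flag; iter hitting the cap or a runaway
  ## coefficient marks non-convergence
  conv <- isTRUE(abs(beta) <= max_abs_beta && fit$iter < 20L)
  list(beta = unname(beta), se = unname(se), converged = conv)
}

#' Covariate-adjusted Cox proportional-hazards fit for one exposure
#'
#' Fits a Cox model of a survival outcome on a single exposure (e.g. the
#' clr abundance of one species, a diversity index, or a risk score) plus an
#' adjustment covariate matrix, using Efron tie handling by default. The
#' Wald test on `beta/se` gives the p-value. Monotone-likelihood/degenerate
#' fits are returned with `converged = FALSE` rather than raising, so
#' callers can exclude them downstream.
#'
#' @param time,event survival time (months) and event indicator (0/1).
#' @param exposure numeric vector; must not be constant.
#' @param covariates optional numeric matrix of adjustment covariates (see
#'   [build_covariates()]).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `beta` (log-HR per exposure unit),
#'   `se`, `hr`, `ci95`, `p`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, exposure, covariates = NULL, ties = "efron") {
  n <- length(time)
  if (length(event) != n || length(exposure) != n)
    stop2("time, event and exposure lengths differ")
  if (!all(event %in% c(0, 1))) stop2("event must be 0/1")
  if (any(time < 0)) stop2("negative survival times")
  if (sum(event) < 2) stop2("need at least 2 events")
  if (length(unique(exposure)) < 2L) stop2("exposure is constant")
  if (!is.null(covariates) && nrow(covariates) != n)
    stop2("covariate rows do not match samples")
  x <- cbind(exposure = exposure, covariates)
  y <- survival::Surv(time, event)
  eng <- cox_engine(x, y, ties = ties)
  beta <- eng$beta; se <- eng$se
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 converged = eng$converged, n = n, n_events = sum(event),
                 ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events/%d samples%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p, x$n_events, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

## --- DerSimonian-Laird pooling -------------------------------------------
## Vectorized core: B and S are species x cohorts matrices of estimates and
## standard errors; NA entries (failed fits) drop out of that species' pool.
dl_pool <- function(B, S) {
  w <- 1 / S^2
  w[!is.finite(w) | is.na(B)] <- NA
  k <- rowSums(!is.na(w))
  sw <- rowSums(w, na.rm = TRUE)
  beta_fixed <- rowSums(w * B, na.rm = TRUE) / sw
  Q <- rowSums(w * (B - beta_fixed)^2, na.rm = TRUE)
  df <- pmax(k - 1, 0)
  denom <- sw - rowSums(w^2, na.rm = TRUE) / sw
  tau2 <- pmax(0, (Q - df) / denom)
  tau2[k <= 1 | denom <= 0] <- 0
  wr <- 1 / (S^2 + tau2)
  wr[!is.finite(wr) | is.na(B)] <- NA
  swr <- rowSums(wr, na.rm = TRUE)
  beta_pooled <- rowSums(wr * B, na.rm = TRUE) / swr
  se_pooled <- sqrt(1 / swr)
  p_het <- ifelse(df >= 1, pchisq(Q, df, lower.tail = FALSE), 1)
  p_meta <- 2 * pnorm(-abs(beta_pooled / se_pooled))
  empty <- k == 0
  for (nm in c("beta_pooled", "se_pooled", "p_meta", "Q", "tau2", "p_het"))
    assign(nm, replace(get(nm), empty, NA_real_))
  list(beta_pooled = beta_pooled, se_pooled = se_pooled, tau2 = tau2,
       q_stat = Q, p_het = p_het, p_meta = p_meta, k = k)
}

#' Random-effects meta-analysis of cohort-specific Cox estimates
#'
#' Pools per-cohort log-hazard-ratios by the DerSimonian-Laird
#' moment estimator: fixed-effect weights `w = 1/se^2` give Cochran's
#' `Q = sum w (beta - beta_fixed)^2`; the between-cohort variance is
#' `tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))`; pooling then uses
#' weights `1/(se^2 + tau^2)`. Heterogeneity p comes from `Q ~ chisq(df)`
#' and the pooled p from a two-sided normal test. Non-converged fits are
#' excluded; with a single usable study the pooled estimate equals that
#' study's.
#'
#' @param fits list of [cox_fit()] objects (or a data.frame with columns
#'   `beta` and `se`).
#' @return object of class `meta_estimate`: `beta_pooled`, `se_pooled`,
#'   `hr`, `ci95`, `tau2`, `q_stat`, `p_het`, `p_meta`, `k` (studies used).
#' @export
meta_random_effects <- function(fits) {
  if (is.data.frame(fits)) {
    beta <- fits$beta; se <- fits$se
  } else {
    if (length(fits) == 0L) stop2("no fits supplied")
    if (inherits(fits, "cox_fit")) fits <- list(fits)
    conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
    beta <- vapply(fits, `[[`, 0, "beta")[conv]
    se <- vapply(fits, `[[`, 0, "se")[conv]
  }
  if (length(beta) == 0L) stop2("no converged fits to pool")
  r <- dl_pool(matrix(beta, nrow = 1L), matrix(se, nrow = 1L))
  structure(list(beta_pooled = r$beta_pooled, se_pooled = r$se_pooled,
                 hr = exp(r$beta_pooled),
                 ci95 = exp(r$beta_pooled + c(-1, 1) * 1.96 * r$se_pooled),
                 tau2 = r$tau2, q_stat = r$q_stat, p_het = r$p_het,
                 p_meta = r$p_meta, k = r$k),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("Random-effects pooled HR = %.3f (95%% CI %.3f-%.3f), p_meta = %.3g\n",
              x$hr, x$ci95[1], x$ci95[2], x$p_meta))
  cat(sprintf("  k = %d, tau2 = %.4f, Q = %.3f, p_het = %.3g\n",
              x$k, x$tau2, x$q_stat, x$p_het))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop2("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop2("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}
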