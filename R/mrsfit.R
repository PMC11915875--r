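#' Full-data per-species Cox associations with meta-analytic pooling
#'
#' Fits the covariate-adjusted Cox model for every species in every cohort
#' on the full data and pools the cohort estimates by DerSimonian-Laird
#' random-effects meta-analysis.
#'
#' @param clr pooled samples x species clr matrix.
#' @param metadata data.frame with `sample_id`, `cohort`, outcome and
#'   covariate columns.
#' @param outcome `"os"` or `"rfs"`.
#' @param covariates covariate names for [build_covariates()].
#' @param ties Cox tie handling.
#' @return data.frame, one row per species: per-cohort `beta`/`se`/`p`
#'   columns, `beta_pooled`, `se_pooled`, `hr`, `ci_low`, `ci_high`,
#'   `tau2`, `q_stat`, `p_het`, `p_meta`, `k_cohorts`.
#' @export
species_associations <- function(clr, metadata, outcome = c("os", "rfs"),
                                 covariates = c("age", "sex", "stage", "smoking"),
                                 ties = "efron") {
  outcome <- match.arg(outcome)
  designs <- cohort_designs(clr, metadata, outcome, covariates)
  r <- fit_all_species(designs, ties = ties)
  species <- colnames(clr) %||% as.character(seq_len(ncol(clr)))
  out <- data.frame(species = species, row.names = NULL)
  for (g in seq_along(designs)) {
    nm <- names(designs)[g]
    out[[paste0("beta_", nm)]] <- r$B[, g]
    out[[paste0("se_", nm)]] <- r$S[, g]
    out[[paste0("p_", nm)]] <- 2 * pnorm(-abs(r$B[, g] / r$S[, g]))
  }
  out$beta_pooled <- r$beta_pooled
  out$se_pooled <- r$se_pooled
  out$hr <- exp(r$beta_pooled)
  out$ci_low <- exp(r$beta_pooled - 1.96 * r$se_pooled)
  out$ci_high <- exp(r$beta_pooled + 1.96 * r$se_pooled)
  out$tau2 <- r$tau2
  out$q_stat <- r$q_stat
  out$p_het <- r$p_het
  out$p_meta <- r$p_meta
  out$k_cohorts <- r$k
  out
}

#' Fit a Microbial Risk Score model to two-cohort microbiome survival data
#'
#' The main modelling interface of the package. Runs the full estimation
#' path on a pooled samples x taxa count matrix and per-sample metadata:
#'
#' 1. taxa filtering by prevalence and mean relative abundance
#'    ([filter_taxa()]), computed on the pooled cohorts;
#' 2. clr normalization ([clr_transform()]) and optional per-cohort batch
#'    centering ([batch_center()]);
#' 3. full-data per-species covariate-adjusted Cox fits per cohort, pooled
#'    by DerSimonian-Laird meta-analysis ([species_associations()]);
#' 4. stability selection over repeated within-cohort subsamples
#'    ([stability_select()]);
#' 5. a permutation-defined p-value on the selection frequency with BH
#'    q-values ([permutation_test()]; skipped when `n_perm = 0`);
#' 6. construction of the weighted, z-scored Microbial Risk Score from the
#'    selected species ([build_mrs()]) and its evaluation by pooled Cox
#'    models and median-split Kaplan-Meier/log-rank analysis.
#'
#' @param counts pooled samples x taxa non-negative integer matrix with
#'   sample rownames and taxon colnames.
#' @param metadata data.frame with columns `sample_id`, `cohort`, `age`,
#'   `sex`, `stage`, `smoking`, `os_time`, `os_event`, `rfs_time`,
#'   `rfs_event`.
#' @param outcome `"os"` (overall survival) or `"rfs"` (relapse-free
#'   survival).
#' @param covariates adjustment covariates.
#' @param filter a [filter_spec()].
#' @param pseudocount clr pseudocount (default 1).
#' @param center_batches apply per-cohort batch centering (default TRUE).
#' @param n_iter,subsample_frac,alpha,threshold stability-selection knobs
#'   (defaults 100, 0.9, 0.05, 0.60).
#' @param n_perm permutations for the selection p-value (default 500; 0
#'   skips the permutation stage).
#' @param seed master RNG seed; subsampling and permutation streams are
#'   derived from it.
#' @param ties Cox tie handling.
#' @return object of class `mrs_fit` with components `associations`
#'   (per-species table including `o_j`, `selected`, `p_perm`, `q_value`),
#'   `selection`, `permutation`, `mrs` (the `mrs_vector`), `mrs_cox`,
#'   `km`, `filter_report`, `clr`, `metadata`, `config`, `call`. Methods:
#'   `print`, `summary`, `coef` (selected-species weights), `predict`
#'   (scores for new samples) and `plot` (median-split KM curves).
#' @examples
#' sim <- simulate_cohorts(sim_config(n_per_cohort = c(60, 40), n_taxa = 40,
#'                                    n_causal = 4, seed = 7))
#' fit <- mrs_fit(sim$counts, sim$metadata, outcome = "os",
#'                n_iter = 20, n_perm = 0, seed = 7)
#' print(fit)
#' @export
mrs_fit <- function(counts, metadata, outcome = c("os", "rfs"),
                    covariates = c("age", "sex", "stage", "smoking"),
                    filter = filter_spec(), pseudocount = 1,
                    center_batches = TRUE,
                    n_iter = 100, subsample_frac = 0.9, alpha = 0.05,
                    threshold = 0.60, n_perm = 500, seed = 1,
                    ties = "efron") {
  outcome <- match.arg(outcome)
  cl <- match.call()
  meta <- align_meta(counts, metadata)

  flt <- filter_taxa(counts, filter)
  clr <- clr_transform(flt$counts, pseudocount)
  if (center_batches && length(unique(meta$cohort)) > 1L)
    clr <- batch_center(clr, meta$cohort)

  assoc <- species_associations(clr, meta, outcome, covariates, ties)

  seeds <- derive_seeds(seed, 2L)
  sel <- stability_select(clr, meta, outcome, covariates,
                          n_iter = n_iter, frac = subsample_frac,
                          alpha = alpha, threshold = threshold,
                          seed = seeds[1], ties = ties)
  assoc$o_j <- sel$table$o_j
  assoc$selected <- sel$table$selected

  perm <- NULL
  if (n_perm > 0) {
    perm <- permutation_test(clr, meta, sel, n_perm = n_perm, seed = seeds[2])
    assoc$p_perm <- perm$table$p_perm
    assoc$q_value <- perm$table$q_value
  }

  mrs <- NULL; mcx <- NULL; km <- NULL
  if (any(assoc$selected)) {
    tag <- if (outcome == "os") "Mortality" else "Relapse"
    mrs <- build_mrs(clr, sel, assoc, outcome_tag = tag)
    mcx <- cox_mrs(mrs, meta, outcome, covariates, ties = ties)
    km <- km_logrank(mrs, meta[[paste0(outcome, "_time")]],
                     meta[[paste0(outcome, "_event")]])
  }

  structure(list(associations = assoc, selection = sel, permutation = perm,
                 mrs = mrs, mrs_cox = mcx, km = km,
                 filter_report = flt$report, clr = clr, metadata = meta,
                 config = list(outcome = outcome, covariates = covariates,
                               filter = filter, pseudocount = pseudocount,
                               center_batches = center_batches,
                               n_iter = n_iter, subsample_frac = subsample_frac,
                               alpha = alpha, threshold = threshold,
                               n_perm = n_perm, seed = seed, ties = ties),
                 call = cl),
            class = "mrs_fit")
}

#' @export
print.mrs_fit <- function(x, ...) {
  cfg <- x$config
  cat("Microbial Risk Score model (", toupper(cfg$outcome), ")\n", sep = "")
  cat(sprintf("  %d samples (%s), %d/%d taxa retained by filter\n",
              nrow(x$clr),
              paste(sprintf("%s: %d", names(table(x$metadata$cohort)),
                            table(x$metadata$cohort)), collapse = ", "),
              ncol(x$clr), nrow(x$filter_report)))
  nsel <- sum(x$associations$selected)
  cat(sprintf("  stability selection: %d species with O_j >= %.2f (%d x %.0f%% subsamples)\n",
              nsel, cfg$threshold, cfg$n_iter, 100 * cfg$subsample_frac))
  if (!is.null(x$mrs_cox))
    cat(sprintf("  MRS: HR per SD = %.3f, median-split log-rank p = %.3g\n",
                x$mrs_cox$hr_per_sd, x$km$logrank_p))
  else
    cat("  no species selected; no MRS built\n")
  invisible(x)
}

#' Summarize a fitted Microbial Risk Score model
#'
#' @param object an `mrs_fit`.
#' @param ... unused.
#' @return invisibly, the selected-species association table.
#' @export
summary.mrs_fit <- function(object, ...) {
  print(object)
  tab <- object$associations
  sel <- tab[tab$selected, , drop = FALSE]
  if (nrow(sel)) {
    cat("\nSelected species:\n")
    show <- sel[order(-sel$o_j),
                intersect(c("species", "hr", "ci_low", "ci_high", "p_meta",
                            "p_het", "o_j", "p_perm", "q_value"), names(sel))]
    print(format(show, digits = 3), row.names = FALSE)
  }
  if (!is.null(object$mrs_cox)) {
    cat("\n")
    print(object$mrs_cox)
    print(object$km)
  }
  invisible(sel)
}

#' Selected-species weights of a fitted MRS model
#'
#' @param object an `mrs_fit`.
#' @param ... unused.
#' @return named numeric vector of pooled log-HR weights (empty when no
#'   species was selected).
#' @export
coef.mrs_fit <- function(object, ...) {
  if (is.null(object$mrs)) return(setNames(numeric(0), character(0)))
  object$mrs$weights
}

#' Score new samples with a fitted MRS model
#'
#' Applies the training-time taxa set, pseudocount, weights and z-scoring
#' (training center/scale) to a new count matrix. No batch centering is
#' applied to new data.
#'
#' @param object an `mrs_fit`.
#' @param newdata samples x taxa count matrix containing at least the
#'   selected species' columns; defaults to the training scores.
#' @param ... unused.
#' @return named numeric vector of z-scored risk scores.
#' @export
predict.mrs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$mrs)) stop2("model has no selected species")
  if (is.null(newdata)) return(object$mrs$score)
  w <- object$mrs$weights
  miss <- setdiff(names(w), colnames(newdata))
  if (length(miss)) stop2("newdata lacks selected species: ",
                          paste(head(miss, 5), collapse = ", "))
  check_matrix(newdata, "newdata")
  clr <- clr_transform(newdata, object$config$pseudocount)
  raw <- drop(clr[, names(w), drop = FALSE] %*% w)
  (raw - object$mrs$center) / object$mrs$scale
}

#' Plot median-split Kaplan-Meier curves of a fitted MRS model
#'
#' @param x an `mrs_fit` with a built MRS.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mrs_fit <- function(x, ...) {
  if (is.null(x$km)) stop2("model has no selected species; nothing to plot")
  cur <- x$km$curves
  cols <- c(low = "#3B6FB6", high = "#C23B55")
  plot(NA, xlim = c(0, max(cur$time)), ylim = c(0, 1),
       xlab = "Months", ylab = "Survival probability",
       main = sprintf("MRS median split (%s)", toupper(x$config$outcome)), ...)
  for (g in c("low", "high")) {
    cc <- cur[cur$group == g, ]
    lines(c(0, cc$time), c(1, cc$surv), type = "s", col = cols[[g]], lwd = 2)
  }
  abline(h = 0.5, lty = 3, col = "grey60")
  legend("topright", legend = sprintf("%s risk", c("low", "high")),
         col = cols, lwd = 2, bty = "n")
  invisible(x)
}
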