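## Build per-cohort design lists used by the subsampling loops:
## one element per cohort with time, event, X (samples x species clr) and
## Z (covariate matrix).
cohort_designs <- function(clr, metadata, outcome = c("os", "rfs"),
                           covariates = c("age", "sex", "stage", "smoking")) {
  outcome <- match.arg(outcome)
  meta <- align_meta(clr, metadata)
  time <- meta[[paste0(outcome, "_time")]]
  event <- meta[[paste0(outcome, "_event")]]
  if (is.null(time) || is.null(event))
    stop2("metadata lacks ", outcome, "_time/", outcome, "_event columns")
  cohorts <- as.character(meta$cohort %||% "cohort1")
  lapply(split(seq_len(nrow(clr)), cohorts), function(idx) {
    m <- meta[idx, , drop = FALSE]
    list(time = time[idx], event = event[idx],
         X = clr[idx, , drop = FALSE],
         Z = if (length(covariates)) build_covariates(m, covariates) else NULL,
         n = length(idx))
  })
}

## Fit every species in every cohort on given per-cohort row indices and
## meta-analyze. Returns the dl_pool list (vectors over species) plus the
## count of failed per-cohort fits.
fit_all_species <- function(designs, rows = NULL, ties = "efron") {
  n_species <- ncol(designs[[1L]]$X)
  k <- length(designs)
  B <- matrix(NA_real_, n_species, k)
  S <- matrix(NA_real_, n_species, k)
  failed <- 0L
  for (g in seq_len(k)) {
    d <- designs[[g]]
    idx <- if (is.null(rows)) seq_len(d$n) else rows[[g]]
    time <- d$time[idx]; event <- d$event[idx]
    if (sum(event) < 2L) { failed <- failed + n_species; next }
    y <- survival::Surv(time, event)
    Z <- if (is.null(d$Z)) NULL else d$Z[idx, , drop = FALSE]
    if (!is.null(Z)) { # drop covariates made constant by subsampling
      keep <- apply(Z, 2L, function(z) length(unique(z)) > 1L)
      Z <- Z[, keep, drop = FALSE]
      if (ncol(Z) == 0L) Z <- NULL
    }
    x <- cbind(numeric(length(idx)), Z)
    for (j in seq_len(n_species)) {
      ex <- d$X[idx, j]
      if (length(unique(ex)) < 2L) { failed <- failed + 1L; next }
      x[, 1L] <- ex
      eng <- cox_engine(x, y, ties = ties)
      if (eng$converged) {
        B[j, g] <- eng$beta
        S[j, g] <- eng$se
      } else failed <- failed + 1L
    }
  }
  out <- dl_pool(B, S)
  out$B <- B; out$S <- S
  out$failed_fits <- failed
  out
}

## One pass of the subsampling frequency computation using the current RNG
## stream: returns the fraction of iterations each species reached
## p_meta < alpha, plus per-iteration failure counts.
selection_frequencies <- function(designs, n_iter, frac, alpha, ties = "efron") {
  n_species <- ncol(designs[[1L]]$X)
  hits <- numeric(n_species)
  failures <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    rows <- lapply(designs, function(d) sample(d$n, floor(frac * d$n)))
    r <- fit_all_species(designs, rows)
    sig <- !is.na(r$p_meta) & r$p_meta < alpha
    hits <- hits + sig
    failures[it] <- r$failed_fits
  }
  list(freq = hits / n_iter, failures = failures)
}

#' Stability selection of survival-associated species by repeated subsampling
#'
#' For each of `n_iter` iterations a fraction `frac` of samples is drawn
#' without replacement within each cohort; every species is then fitted with
#' a covariate-adjusted Cox model per cohort and pooled by random-effects
#' meta-analysis, and species reaching `p_meta < alpha` are marked. The
#' selection frequency `O_j` is the fraction of iterations in which species
#' `j` was marked; species with `O_j >= threshold` are selected. Iterations
#' in which a cohort's subsample has fewer than 2 events (or a fit fails to
#' converge) contribute "not marked" for the affected fits and are counted
#' in the failure log rather than silently dropped.
#'
#' @param clr pooled samples x species clr matrix (rownames = sample IDs).
#' @param metadata data.frame with `sample_id`, `cohort`, outcome columns
#'   and the adjustment covariates.
#' @param outcome `"os"` or `"rfs"`.
#' @param covariates covariate names passed to [build_covariates()].
#' @param n_iter number of subsampling iterations (default 100).
#' @param frac subsampled fraction per cohort (default 0.9).
#' @param alpha within-iteration significance level on `p_meta`
#'   (default 0.05).
#' @param threshold selection frequency cutoff (default 0.60).
#' @param seed RNG seed.
#' @param ties Cox tie handling.
#' @return object of class `selection_result`: data.frame `table`
#'   (species, `o_j`, `selected`) plus the knobs and a per-iteration
#'   failed-fit count.
#' @export
stability_select <- function(clr, metadata, outcome = c("os", "rfs"),
                             covariates = c("age", "sex", "stage", "smoking"),
                             n_iter = 100, frac = 0.9, alpha = 0.05,
                             threshold = 0.60, seed = 1, ties = "efron") {
  outcome <- match.arg(outcome)
  if (frac <= 0 || frac > 1) stop2("frac must lie in (0, 1]")
  designs <- cohort_designs(clr, metadata, outcome, covariates)
  set.seed(seed)
  r <- selection_frequencies(designs, n_iter, frac, alpha, ties)
  species <- colnames(clr) %||% as.character(seq_len(ncol(clr)))
  structure(list(table = data.frame(species = species, o_j = r$freq,
                                    selected = r$freq >= threshold,
                                    row.names = NULL),
                 n_iter = n_iter, frac = frac, alpha = alpha,
                 threshold = threshold, seed = seed, outcome = outcome,
                 covariates = covariates, ties = ties,
                 failed_fits = r$failures),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  sel <- x$table[x$table$selected, , drop = FALSE]
  cat(sprintf("Stability selection (%s): %d/%d species selected (O_j >= %.2f over %d x %.0f%% subsamples)\n",
              toupper(x$outcome), nrow(sel), nrow(x$table), x$threshold,
              x$n_iter, 100 * x$frac))
  if (nrow(sel)) {
    sel <- sel[order(-sel$o_j), ]
    print(head(sel, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Permutation-defined p-values for stability-selection frequencies
#'
#' Repeats the full subsampling frequency computation of
#' [stability_select()] on data in which the outcome pairs (time, event)
#' are randomly permuted against the exposure/covariate rows within each
#' cohort, yielding permuted frequencies `P_ij` for permutation `i` and
#' species `j`. The p-value is
#' `p_j = (sum_i I(P_ij >= O_j) + 1) / (n_perm + 1)`, bounded below by
#' `1/(n_perm + 1)`, and Benjamini-Hochberg q-values are computed across
#' species.
#'
#' @param clr,metadata as in [stability_select()].
#' @param observed a `selection_result` from [stability_select()]; its
#'   knobs (`n_iter`, `frac`, `alpha`, covariates, outcome, ties) are
#'   reused for every permutation.
#' @param n_perm number of outcome permutations (default 500).
#' @param seed RNG seed (independent of the observed run's).
#' @return object of class `permutation_summary`: data.frame `table`
#'   (species, `o_j`, `p_perm`, `q_value`), the permuted frequency matrix
#'   `P` (n_perm x species), `n_perm`, `seed`.
#' @export
permutation_test <- function(clr, metadata, observed, n_perm = 500, seed = 1) {
  stopifnot(inherits(observed, "selection_result"))
  if (n_perm < 1) stop2("n_perm must be at least 1")
  designs <- cohort_designs(clr, metadata, observed$outcome, observed$covariates)
  o_j <- observed$table$o_j
  set.seed(seed)
  P <- matrix(NA_real_, n_perm, length(o_j),
              dimnames = list(NULL, observed$table$species))
  for (i in seq_len(n_perm)) {
    perm <- lapply(designs, function(d) {
      pi <- sample(d$n)
      d$time <- d$time[pi]
      d$event <- d$event[pi]
      d
    })
    P[i, ] <- selection_frequencies(perm, observed$n_iter, observed$frac,
                                    observed$alpha, observed$ties)$freq
  }
  exceed <- colSums(P >= rep(o_j, each = n_perm))
  p_perm <- (exceed + 1) / (n_perm + 1)
  structure(list(table = data.frame(species = observed$table$species,
                                    o_j = o_j, p_perm = p_perm,
                                    q_value = bh_fdr(p_perm),
                                    row.names = NULL),
                 P = P, n_perm = n_perm, seed = seed,
                 outcome = observed$outcome),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation test (%s): %d permutations, p floor %.4g\n",
              toupper(x$outcome), x$n_perm, 1 / (x$n_perm + 1)))
  tab <- x$table[order(x$table$p_perm), ]
  print(head(tab, 10), row.names = FALSE)
  invisible(x)
}
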