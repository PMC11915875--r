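#' Alpha-diversity indices per sample
#'
#' Computes observed richness, bias-corrected Chao1
#' `S_obs + F1*(F1-1)/(2*(F2+1))` (F1/F2 = singleton/doubleton counts),
#' Shannon entropy `-sum p log p` (natural log) and Gini-Simpson
#' `1 - sum p^2`. Shannon and Simpson are delegated to
#' [vegan::diversity()].
#'
#' @param counts samples x taxa non-negative integer matrix; no sample may
#'   be all zero.
#' @return data.frame with columns `sample_id`, `observed`, `chao1`,
#'   `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts) {
  check_matrix(counts, "counts", integer = TRUE)
  if (any(rowSums(counts) == 0))
    stop2("all-zero sample(s): ",
          paste(head(which(rowSums(counts) == 0), 5), collapse = ", "))
  f1 <- rowSums(counts == 1L)
  f2 <- rowSums(counts == 2L)
  observed <- rowSums(counts > 0L)
  chao1 <- observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  data.frame(sample_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             observed = observed,
             chao1 = chao1,
             shannon = vegan::diversity(counts, index = "shannon"),
             simpson = vegan::diversity(counts, index = "simpson"),
             row.names = NULL)
}

#' Rank tests and adjusted linear models for alpha diversity by group
#'
#' For each diversity index, compares groups with a Wilcoxon rank-sum test
#' (two groups) or Kruskal-Wallis test (more) and additionally fits a linear
#' model of the index on the grouping, adjusted for a covariate matrix,
#' reporting the group term's F-test p-value.
#'
#' @param alpha data.frame from [alpha_diversity()] (or any data.frame of
#'   numeric index columns plus `sample_id`).
#' @param grouping factor/vector aligned to the rows of `alpha`.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @param indices columns of `alpha` to test.
#' @return data.frame: index, test used, statistic, p, adjusted-model p.
#' @export
alpha_group_tests <- function(alpha, grouping, covariates = NULL,
                              indices = c("chao1", "shannon", "simpson")) {
  grouping <- factor(grouping)
  if (length(grouping) != nrow(alpha))
    stop2("grouping length does not match alpha rows")
  tab <- table(grouping)
  if (length(tab) < 2L) stop2("need at least two groups")
  if (any(tab < 2L)) stop2("each group needs at least 2 samples")
  rows <- lapply(indices, function(ix) {
    y <- alpha[[ix]]
    if (is.null(y)) stop2("index column '", ix, "' not found")
    if (length(unique(y)) == 1L) {
      ## all values tie: no rank information, statistic 0 by convention
      ht <- list(statistic = 0, p.value = 1)
      test <- if (length(tab) == 2L) "wilcoxon" else "kruskal-wallis"
    } else if (length(tab) == 2L) {
      ht <- suppressWarnings(wilcox.test(y ~ grouping))
      test <- "wilcoxon"
    } else {
      ht <- kruskal.test(y ~ grouping)
      test <- "kruskal-wallis"
    }
    lm_p <- NA_real_
    if (length(unique(y)) > 1L) {
      dat <- data.frame(y = y, g = grouping)
      if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
      av <- anova(lm(y ~ ., data = dat))
      lm_p <- av[["Pr(>F)"]][rownames(av) == "g"]
    }
    data.frame(index = ix, test = test,
               statistic = unname(ht$statistic), p = ht$p.value,
               lm_p = lm_p)
  })
  do.call(rbind, rows)
}

## Shannon entropy of rows of a relative-abundance matrix (0 log 0 = 0)
row_entropy <- function(p) {
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

#' Jensen-Shannon divergence matrix
#'
#' Pairwise JSD between samples' relative-abundance profiles,
#' `JSD(p,q) = H((p+q)/2) - (H(p)+H(q))/2` with natural-log entropy `H`.
#' Values lie in `[0, log 2]`; the matrix is symmetric with zero diagonal
#' and `sqrt(JSD)` is a metric.
#'
#' @param counts samples x taxa non-negative matrix (counts or proportions).
#' @return symmetric samples x samples matrix of JSD values.
#' @export
jsd_matrix <- function(counts) {
  check_matrix(counts, "counts")
  totals <- rowSums(counts)
  if (any(totals == 0)) stop2("zero-sum sample(s) cannot be normalized")
  p <- counts / totals
  n <- nrow(p)
  h <- row_entropy(p)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    ## entropy of midpoints of sample i with all later samples
    m <- sweep(p[(i + 1L):n, , drop = FALSE], 2L, p[i, ], "+") / 2
    hm <- row_entropy(m)
    d <- hm - (h[(i + 1L):n] + h[i]) / 2
    d <- pmin(pmax(d, 0), log(2)) # clamp fp noise at the bounds
    out[i, (i + 1L):n] <- d
    out[(i + 1L):n, i] <- d
  }
  out
}

#' Distance-based PERMANOVA with covariates fitted first
#'
#' Partitions the sums of squares of a distance matrix (McArdle-Anderson
#' Gower-centered form) sequentially: adjustment covariates first, then the
#' variable of interest. Significance comes from permuting the variable's
#' values only -- covariates stay attached to samples -- optionally within
#' strata (e.g. cohorts), with
#' `p = (#\{permuted F >= observed F\} + 1) / (n_perm + 1)`.
#'
#' @param d distance matrix (`dist` or square symmetric matrix), e.g. from
#'   [jsd_matrix()].
#' @param variable vector aligned to samples; factor or numeric.
#' @param covariates optional numeric matrix of covariates, fitted before
#'   `variable`.
#' @param strata optional vector of permutation strata labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return object of class `permanova`: list with `f`, `p`, `df`, the
#'   sums-of-squares table, `n_perm` and `seed`.
#' @export
permanova <- function(d, variable, covariates = NULL, strata = NULL,
                      n_perm = 10000, seed = 1) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop2("d must be square")
  n <- nrow(D)
  if (length(variable) != n) stop2("variable must have one value per sample")
  if (length(unique(variable)) < 2L) stop2("variable is constant")
  if (n_perm < 99) stop2("n_perm must be at least 99")
  if (!is.null(strata) && length(strata) != n)
    stop2("strata must have one label per sample")

  A <- -0.5 * D^2
  G <- sweep(A, 1L, rowMeans(A))
  G <- sweep(G, 2L, colMeans(G)) # double-centered Gower matrix
  sst <- sum(diag(G))

  Xc <- cbind(rep(1, n), covariates)
  qc <- qr(Xc)
  Qc <- qr.Q(qc)[, seq_len(qc$rank), drop = FALSE]
  ss_cov <- sum(Qc * (G %*% Qc))

  expand_var <- function(v) {
    if (is.numeric(v)) matrix(v, ncol = 1L) else model.matrix(~v)[, -1, drop = FALSE]
  }
  fstat <- function(v) {
    Xf <- cbind(Xc, expand_var(v))
    qf <- qr(Xf)
    Qf <- qr.Q(qf)[, seq_len(qf$rank), drop = FALSE]
    ss_full <- sum(Qf * (G %*% Qf))
    df_var <- qf$rank - qc$rank
    df_res <- n - qf$rank
    ss_var <- ss_full - ss_cov
    ss_res <- sst - ss_full
    c(f = (ss_var / df_var) / (ss_res / df_res),
      ss_var = ss_var, ss_res = ss_res, df_var = df_var, df_res = df_res)
  }
  obs <- fstat(variable)
  if (obs["df_var"] < 1) stop2("variable adds no rank beyond the covariates")

  set.seed(seed)
  perm_one <- function() {
    if (is.null(strata)) return(sample(variable))
    v <- variable
    for (g in unique(strata)) {
      idx <- which(strata == g)
      v[idx] <- v[idx][sample(length(idx))]
    }
    v
  }
  fperm <- vapply(seq_len(n_perm), function(i) fstat(perm_one())[["f"]], 0)
  p <- (sum(fperm >= obs[["f"]]) + 1) / (n_perm + 1)
  structure(list(f = obs[["f"]], p = p,
                 df = c(variable = obs[["df_var"]], residual = obs[["df_res"]]),
                 ss = c(covariates = ss_cov, variable = obs[["ss_var"]],
                        residual = obs[["ss_res"]], total = sst),
                 n_perm = n_perm, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential, covariates first)\n")
  cat(sprintf("  pseudo-F = %.4f on %d and %d df;  p = %.4g  (%d permutations)\n",
              x$f, x$df["variable"], x$df["residual"], x$p, x$n_perm))
  invisible(x)
}

## multivariate hypergeometric draw: subsample d reads without replacement
## from a count vector x
rmhyper <- function(x, d) {
  out <- integer(length(x))
  remaining <- sum(x)
  for (t in seq_along(x)) {
    if (d == 0L) break
    k <- stats::rhyper(1L, x[t], remaining - x[t], d)
    out[t] <- k
    d <- d - k
    remaining <- remaining - x[t]
  }
  out
}

#' Rarefaction curves by repeated subsampling
#'
#' Expected observed richness at each depth, estimated as the mean richness
#' over `n_draws` subsamples drawn without replacement from each sample's
#' reads. The expectation has the closed form
#' `E[S(d)] = sum_t (1 - choose(N - n_t, d)/choose(N, d))`, which the Monte
#' Carlo estimate approaches as `n_draws` grows.
#'
#' @param counts samples x taxa non-negative integer matrix.
#' @param depths increasing vector of subsampling depths; each must not
#'   exceed the total of any sample it is evaluated on.
#' @param n_draws subsamples per depth (default 25).
#' @param seed RNG seed.
#' @return data.frame: sample_id, depth, richness (mean over draws).
#' @export
rarefaction_curves <- function(counts, depths, n_draws = 25, seed = 1) {
  check_matrix(counts, "counts", integer = TRUE)
  totals <- rowSums(counts)
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) stop2("depths must be positive")
  set.seed(seed)
  rows <- list()
  for (s in seq_len(nrow(counts))) {
    for (d in depths) {
      if (d > totals[s])
        stop2("depth ", d, " exceeds total ", totals[s], " of sample ",
              rownames(counts)[s] %||% s)
      rich <- mean(vapply(seq_len(n_draws),
                          function(i) sum(rmhyper(counts[s, ], d) > 0L), 0))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = rownames(counts)[s] %||% as.character(s),
                   depth = d, richness = rich)
    }
  }
  do.call(rbind, rows)
}
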