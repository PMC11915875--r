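#' Binarize a numeric vector at its median
#'
#' Values strictly above the median become 1 ("high"), values at or below
#' it become 0 ("low"); ties at the median therefore fall in the low group.
#'
#' @param values numeric vector with at least two distinct values.
#' @return integer 0/1 vector.
#' @export
binarize_by_median <- function(values) {
  if (anyNA(values)) stop2("missing values")
  if (length(unique(values)) < 2L) stop2("constant vector cannot be binarized")
  as.integer(values > median(values))
}

## fit one logistic model, returning OR, Wald CI, p and a separation flag
logistic_one <- function(y, score, Z) {
  dat <- data.frame(y = y, score = score)
  if (!is.null(Z)) dat <- cbind(dat, as.data.frame(Z))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  b <- co["score", "Estimate"]; se <- co["score", "Std. Error"]
  if (abs(b) > 15 || se > 100) sep <- TRUE
  list(or = exp(b), ci95 = if (sep) c(0, Inf) else exp(b + c(-1, 1) * 1.96 * se),
       p = co["score", "Pr(>|z|)"], se = se, separated = sep)
}

#' Logistic association of median-binarized immune variables with an MRS
#'
#' For each immune variable (binarized at its median via
#' [binarize_by_median()]), fits a covariate-adjusted logistic regression on
#' the continuous MRS. Two pooling modes: `"combined"` fits one model with
#' a cohort indicator; `"meta"` fits per cohort and pools the log-odds
#' ratios by DerSimonian-Laird random effects. Separation is flagged and
#' the CI reported as unbounded.
#'
#' @param immune samples x cell-type fraction matrix (or one numeric
#'   vector), sample rownames matching the score names.
#' @param mrs an `mrs_vector` (or plain named numeric scores).
#' @param metadata data.frame with `sample_id`, `cohort` and covariates.
#' @param covariates adjustment covariates.
#' @param mode `"meta"` (default) or `"combined"`.
#' @return data.frame: variable, or, ci_low, ci_high, p, separated (and
#'   p_het in meta mode).
#' @export
logistic_assoc <- function(immune, mrs, metadata,
                           covariates = c("age", "sex", "stage", "smoking"),
                           mode = c("meta", "combined")) {
  mode <- match.arg(mode)
  score <- if (inherits(mrs, "mrs_vector")) mrs$score else mrs
  if (is.null(dim(immune))) immune <- matrix(immune, ncol = 1L,
                                             dimnames = list(names(score), "immune"))
  immune <- immune[names(score), , drop = FALSE]
  meta <- metadata[match(names(score), metadata$sample_id), , drop = FALSE]
  cohorts <- as.character(meta$cohort %||% "cohort1")
  rows <- lapply(colnames(immune), function(v) {
    y <- binarize_by_median(immune[, v])
    if (mode == "combined" || length(unique(cohorts)) < 2L) {
      cvs <- covariates
      m <- meta
      m$cohort_b <- as.numeric(factor(cohorts)) - 1
      Z <- build_covariates(m, c(cvs, if (length(unique(cohorts)) > 1L) "cohort_b"))
      r <- logistic_one(y, score, Z)
      data.frame(variable = v, or = r$or, ci_low = r$ci95[1],
                 ci_high = r$ci95[2], p = r$p, p_het = NA_real_,
                 separated = r$separated)
    } else {
      per <- lapply(split(seq_along(score), cohorts), function(idx) {
        if (length(unique(y[idx])) < 2L) return(NULL)
        Z <- build_covariates(meta[idx, , drop = FALSE], covariates)
        logistic_one(y[idx], score[idx], Z)
      })
      per <- Filter(function(r) !is.null(r) && !r$separated, per)
      if (length(per) == 0L)
        return(data.frame(variable = v, or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_, p_het = NA_real_,
                          separated = TRUE))
      pool <- meta_random_effects(data.frame(beta = vapply(per, function(r) log(r$or), 0),
                                             se = vapply(per, `[[`, 0, "se")))
      data.frame(variable = v, or = pool$hr, ci_low = pool$ci95[1],
                 ci_high = pool$ci95[2], p = pool$p_meta, p_het = pool$p_het,
                 separated = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlations between species clr values and target variables
#'
#' Rank correlation with tie-corrected (asymptotic) p-values for every
#' (species, target) pair, e.g. selected species against immune-cell
#' fractions or gene expression. Constant vectors yield `NA` with a flag.
#'
#' @param clr_columns samples x features numeric matrix (e.g. clr of the
#'   selected species).
#' @param targets samples x targets numeric matrix aligned by rownames.
#' @return data.frame: feature, target, r, p, flagged.
#' @export
spearman_matrix <- function(clr_columns, targets) {
  if (is.null(dim(clr_columns))) clr_columns <- cbind(feature = clr_columns)
  if (is.null(dim(targets))) targets <- cbind(target = targets)
  if (nrow(clr_columns) != nrow(targets))
    stop2("row counts differ between features and targets")
  if (nrow(clr_columns) < 3L) stop2("need at least 3 paired observations")
  rows <- list()
  for (f in colnames(clr_columns)) {
    x <- clr_columns[, f]
    for (t in colnames(targets)) {
      y <- targets[, t]
      if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(feature = f, target = t,
                                                r = NA_real_, p = NA_real_,
                                                flagged = TRUE)
        next
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(feature = f, target = t,
                                              r = unname(ct$estimate),
                                              p = ct$p.value, flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' Upper-tail hypergeometric enrichment p-value per gene set for a query
#' list against a universe, with Benjamini-Hochberg q-values across sets.
#' Genes outside the universe are dropped from each set before testing.
#'
#' @param query_genes character vector; must be a subset of `universe`.
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: set, set_size (within universe), overlap, p,
#'   q_value, overlap_genes.
#' @export
hypergeom_ora <- function(query_genes, universe, gene_sets) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (length(query_genes) == 0L) stop2("empty query gene list")
  bad <- setdiff(query_genes, universe)
  if (length(bad)) stop2("query genes outside universe: ",
                         paste(head(bad, 5), collapse = ", "))
  if (length(gene_sets) == 0L) stop2("no gene sets supplied")
  N <- length(universe); q <- length(query_genes)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    ov <- intersect(query_genes, set)
    k <- length(ov); m <- length(set)
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set = s, set_size = m, overlap = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("set", "set_size", "overlap", "p", "q_value", "overlap_genes")]
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, "", 1L))
}
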