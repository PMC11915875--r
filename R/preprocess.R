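#' Taxa filtering thresholds
#'
#' Defines the retention rule applied before normalization: a taxon is kept
#' when the fraction of samples carrying at least `min_count` reads reaches
#' `min_prevalence` AND its mean relative abundance reaches
#' `min_mean_relab`. Thresholds are inclusive, so a taxon sitting exactly on
#' a boundary is retained.
#'
#' @param min_count minimum reads for a sample to count as "carrying" the
#'   taxon (default 2).
#' @param min_prevalence minimum carrying fraction of samples (default 0.10).
#' @param min_mean_relab minimum mean relative abundance across samples
#'   (default 1e-5, i.e. 0.001%).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(min_count = 2L, min_prevalence = 0.10,
                        min_mean_relab = 1e-5) {
  if (min_count < 1 || min_count != round(min_count))
    stop2("min_count must be a positive integer")
  if (min_prevalence < 0 || min_prevalence > 1)
    stop2("min_prevalence must lie in [0, 1]")
  if (min_mean_relab < 0 || min_mean_relab > 1)
    stop2("min_mean_relab must lie in [0, 1]")
  structure(list(min_count = as.integer(min_count),
                 min_prevalence = min_prevalence,
                 min_mean_relab = min_mean_relab),
            class = "filter_spec")
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Applies the retention rule of [filter_spec()] to a pooled samples x taxa
#' count matrix and reports, for every removed taxon, which rule removed it.
#' Filtering is computed on all samples pooled; pass a subset to filter
#' per cohort.
#'
#' @param counts samples x taxa non-negative integer matrix.
#' @param spec a [filter_spec()].
#' @return list with `counts` (retained columns), `report` (one row per
#'   taxon: prevalence, mean relative abundance, kept flag, removal reason)
#'   and `spec`.
#' @export
filter_taxa <- function(counts, spec = filter_spec()) {
  check_matrix(counts, "counts", integer = TRUE)
  stopifnot(inherits(spec, "filter_spec"))
  totals <- rowSums(counts)
  if (any(totals == 0)) stop2("samples with zero total counts: ",
                              paste(head(which(totals == 0), 5), collapse = ", "))
  prevalence <- colMeans(counts >= spec$min_count)
  mean_relab <- colMeans(counts / totals)
  ok_prev <- prevalence >= spec$min_prevalence
  ok_ab <- mean_relab >= spec$min_mean_relab
  keep <- ok_prev & ok_ab
  reason <- rep("", ncol(counts))
  reason[!ok_prev] <- "prevalence"
  reason[!ok_ab] <- "mean_relab"
  reason[!ok_prev & !ok_ab] <- "prevalence+mean_relab"
  report <- data.frame(taxon = colnames(counts) %||% as.character(seq_len(ncol(counts))),
                       prevalence = prevalence, mean_relab = mean_relab,
                       kept = keep, reason = reason, row.names = NULL)
  if (!any(keep))
    stop2("all ", ncol(counts), " taxa removed by filter (max prevalence ",
          signif(max(prevalence), 3), ", max mean relab ",
          signif(max(mean_relab), 3), ")")
  list(counts = counts[, keep, drop = FALSE], report = report, spec = spec)
}

#' Centered log-ratio transform
#'
#' Per sample, adds a pseudocount to the raw counts and maps the result to
#' clr coordinates: `clr_i = log(x_i + pc) - mean_j log(x_j + pc)`. Rows of
#' the result sum to zero; the transform is invariant to rescaling a
#' sample's counts (with the pseudocount scaled along).
#'
#' @param counts samples x taxa non-negative matrix.
#' @param pseudocount positive value added to every count (default 1).
#' @return samples x taxa matrix of clr values, with the pseudocount kept as
#'   attribute `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  check_matrix(counts, "counts")
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
    stop2("pseudocount must be a single positive number")
  lx <- log(counts + pseudocount)
  out <- lx - rowMeans(lx)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-cohort batch centering of a clr matrix
#'
#' A deliberately simple location adjustment for cohort-level batch shifts:
#' each taxon's per-cohort mean is removed and the grand mean added back, so
#' cohorts share a common per-taxon center afterwards. Row sums (zero for a
#' clr matrix) are preserved. This is a location-only adjustment; it does not
#' attempt distribution-level batch correction.
#'
#' @param clr samples x taxa clr matrix.
#' @param cohort vector of cohort labels aligned to the rows of `clr`.
#' @return centered matrix of the same shape.
#' @export
batch_center <- function(clr, cohort) {
  check_matrix(clr, "clr matrix", nonneg = FALSE)
  if (length(cohort) != nrow(clr))
    stop2("cohort labels (", length(cohort), ") do not match samples (",
          nrow(clr), ")")
  cohort <- as.character(cohort)
  sizes <- table(cohort)
  if (any(sizes < 2L))
    stop2("cohort(s) with fewer than 2 samples: ",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  grand <- colMeans(clr)
  out <- clr
  for (g in unique(cohort)) {
    idx <- which(cohort == g)
    out[idx, ] <- sweep(clr[idx, , drop = FALSE], 2L, colMeans(clr[idx, , drop = FALSE]) - grand)
  }
  attributes(out) <- attributes(clr)
  out
}
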