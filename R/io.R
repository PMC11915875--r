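#' Parse taxonomy lineage strings into rank fields
#'
#' Accepts lineage identifiers of the form
#' `"k__Bacteria|p__Proteobacteria|...|s__Escherichia_coli"` and extracts
#' one column per rank prefix present (k, p, c, o, f, g, s); underscores in
#' the species epithet become spaces. Plain identifiers pass through with
#' all rank fields `NA`.
#'
#' @param ids character vector of taxon identifiers.
#' @return data.frame with columns `taxon_id`, `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`.
#' @export
parse_lineage <- function(ids) {
  ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- data.frame(taxon_id = ids)
  for (r in ranks) out[[r]] <- NA_character_
  for (i in seq_along(ids)) {
    if (!grepl("__", ids[i], fixed = TRUE)) next
    parts <- strsplit(ids[i], "|", fixed = TRUE)[[1L]]
    for (p in parts) {
      pre <- sub("__.*$", "", p)
      if (pre %in% names(ranks))
        out[i, ranks[[pre]]] <- gsub("_", " ", sub("^.__", "", p))
    }
  }
  out
}

#' Read a taxa x samples count TSV
#'
#' Expects taxa in rows and samples in columns, with the first column the
#' taxon identifier (optionally a `k__...|s__...` lineage string) and a
#' header row of sample IDs. Returns the transposed samples x taxa integer
#' matrix; parsed taxonomy ranks (when lineage strings are present) are
#' attached as attribute `"taxonomy"`.
#'
#' @param path TSV file path.
#' @return samples x taxa integer matrix.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop2("counts file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  taxa <- df[[1L]]
  if (anyDuplicated(taxa))
    stop2("duplicate taxon IDs: ",
          paste(unique(taxa[duplicated(taxa)])[1:min(3, sum(duplicated(taxa)))],
                collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop2("duplicate sample columns: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop2("non-numeric count at taxon '", taxa[bad[1L]], "', sample '",
          samples[bad[2L]], "'")
  }
  if (any(num != round(num)) || any(num < 0))
    stop2("counts must be non-negative integers")
  m <- t(num)
  dimnames(m) <- list(samples, taxa)
  storage.mode(m) <- "integer"
  if (any(grepl("__", taxa, fixed = TRUE)))
    attr(m, "taxonomy") <- parse_lineage(taxa)
  m
}

#' Write a samples x taxa count matrix as a taxa x samples TSV
#'
#' @param counts samples x taxa matrix.
#' @param path output TSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(taxon_id = colnames(counts), t(counts),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_required <- c("sample_id", "cohort", "age", "sex", "stage",
                       "smoking", "os_time", "os_event", "rfs_time",
                       "rfs_event")

#' Read and validate a sample metadata TSV
#'
#' One sample per row; required columns: `sample_id`, `cohort`, `age`,
#' `sex`, `stage`, `smoking`, `os_time`, `os_event`, `rfs_time`,
#' `rfs_event`. Missing smoking becomes the explicit `"not_reported"`
#' category. Validation errors name the offending sample: events must be
#' 0/1, times non-negative and `rfs_time <= os_time`.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop2("metadata file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata) {
  miss <- setdiff(metadata_required, names(metadata))
  if (length(miss)) stop2("metadata lacks required column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop2("duplicate sample IDs: ",
          paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                collapse = ", "))
  metadata$smoking <- as.character(metadata$smoking)
  metadata$smoking[is.na(metadata$smoking) | metadata$smoking == ""] <- "not_reported"
  for (ev in c("os_event", "rfs_event")) {
    bad <- !metadata[[ev]] %in% c(0, 1)
    if (any(bad)) stop2(ev, " outside {0,1} for sample(s): ",
                        paste(head(metadata$sample_id[bad], 5), collapse = ", "))
  }
  for (tm in c("os_time", "rfs_time")) {
    bad <- !is.finite(metadata[[tm]]) | metadata[[tm]] < 0
    if (any(bad)) stop2("negative or missing ", tm, " for sample(s): ",
                        paste(head(metadata$sample_id[bad], 5), collapse = ", "))
  }
  bad <- metadata$rfs_time > metadata$os_time + 1e-9
  if (any(bad)) stop2("rfs_time exceeds os_time for sample(s): ",
                      paste(head(metadata$sample_id[bad], 5), collapse = ", "))
  metadata
}

#' Write sample metadata as TSV
#'
#' @param metadata data.frame.
#' @param path output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Writes the pooled counts (taxa x samples TSV), pooled metadata (TSV) and
#' the ground truth (JSON sidecar; the latent clr matrix is omitted).
#'
#' @param sim result of [simulate_cohorts()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, paths[["counts"]])
  write_metadata(sim$metadata, paths[["metadata"]])
  tr <- sim$truth
  jsonlite::write_json(list(causal_taxa = tr$causal_taxa,
                            beta_true = as.list(tr$beta_true),
                            covariate_effects = as.list(tr$covariate_effects),
                            immune_map = as.list(tr$immune_map),
                            seed = tr$seed),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Pipeline configuration
#'
#' Bundles the input paths and knobs for [run_pipeline()]. Referenced files
#' must exist at construction.
#'
#' @param counts,metadata paths to the count and metadata TSVs.
#' @param immune optional path to a samples x cell-type fraction TSV.
#' @param expression optional path to a genes x samples expression TSV.
#' @param gene_sets optional path to a GMT file.
#' @param out_dir output directory.
#' @param outcomes outcomes to analyze.
#' @param filter a [filter_spec()].
#' @param pseudocount,n_iter,subsample_frac,alpha,threshold,n_perm,ties
#'   passed to [mrs_fit()].
#' @param n_perm_permanova permutations for the beta-diversity test.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, immune = NULL,
                            expression = NULL, gene_sets = NULL,
                            out_dir = "mrsurv_out",
                            outcomes = c("os", "rfs"),
                            filter = filter_spec(), pseudocount = 1,
                            n_iter = 100, subsample_frac = 0.9,
                            alpha = 0.05, threshold = 0.60, n_perm = 500,
                            n_perm_permanova = 999, ties = "efron",
                            seed = 1) {
  for (p in c(counts, metadata, immune, expression, gene_sets))
    if (!file.exists(p)) stop2("input file not found: ", p)
  stopifnot(all(outcomes %in% c("os", "rfs")),
            n_iter >= 1, n_perm >= 0, subsample_frac > 0, subsample_frac <= 1,
            alpha > 0, alpha < 1, threshold >= 0, threshold <= 1)
  structure(list(counts = counts, metadata = metadata, immune = immune,
                 expression = expression, gene_sets = gene_sets,
                 out_dir = out_dir, outcomes = outcomes, filter = filter,
                 pseudocount = pseudocount, n_iter = n_iter,
                 subsample_frac = subsample_frac, alpha = alpha,
                 threshold = threshold, n_perm = n_perm,
                 n_perm_permanova = n_perm_permanova, ties = ties,
                 seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline over TSV inputs
#'
#' Orchestrates preprocessing, diversity summaries, the per-outcome MRS
#' model ([mrs_fit()]) and, when immune/expression inputs are provided, the
#' immune-association stage. All reports are written as TSV/JSON under the
#' configured output directory together with a manifest recording the
#' package version, seed, config fingerprint and the written files. Rerun
#' with the same config and seed reproduces identical reports.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop2("[stage ", name, "] ", conditionMessage(e)))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- write_tsv(df, file.path(config$out_dir, name))
    outputs[[name]] <<- p
  }

  counts <- stage("read", read_counts(config$counts))
  metadata <- read_metadata(config$metadata)
  metadata <- align_meta(counts, metadata)
  seeds <- derive_seeds(config$seed, 4L)

  ## diversity on the unfiltered counts
  alpha <- stage("alpha_diversity", alpha_diversity(counts))
  emit(alpha, "alpha_diversity.tsv")
  Z <- build_covariates(metadata)
  atests <- stage("alpha_tests", {
    rbind(cbind(grouping = "stage",
                alpha_group_tests(alpha, metadata$stage, Z)),
          cbind(grouping = "os_event",
                alpha_group_tests(alpha, metadata$os_event, Z)))
  })
  emit(atests, "alpha_group_tests.tsv")
  alpha_cox <- stage("alpha_survival", {
    do.call(rbind, lapply(config$outcomes, function(oc) {
      do.call(rbind, lapply(c("chao1", "shannon", "simpson"), function(ix) {
        f <- cox_fit(metadata[[paste0(oc, "_time")]],
                     metadata[[paste0(oc, "_event")]], alpha[[ix]], Z)
        data.frame(outcome = oc, index = ix, hr = f$hr, ci_low = f$ci95[1],
                   ci_high = f$ci95[2], p = f$p)
      }))
    }))
  })
  emit(alpha_cox, "alpha_survival.tsv")

  beta <- stage("jsd", jsd_matrix(counts))
  emit(data.frame(sample_id = rownames(beta), beta, check.names = FALSE),
       "jsd_matrix.tsv")
  pmv <- stage("permanova", permanova(beta, metadata$os_event,
                                      covariates = Z,
                                      strata = metadata$cohort,
                                      n_perm = config$n_perm_permanova,
                                      seed = seeds[1]))
  jsonlite::write_json(list(variable = "os_event", f = pmv$f, p = pmv$p,
                            df = as.list(pmv$df), n_perm = pmv$n_perm),
                       file.path(config$out_dir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs[["permanova.json"]] <- file.path(config$out_dir, "permanova.json")

  ## per-outcome MRS models
  fits <- list()
  summaries <- list()
  for (i in seq_along(config$outcomes)) {
    oc <- config$outcomes[i]
    fit <- stage(paste0("mrs_fit_", oc),
                 mrs_fit(counts, metadata, outcome = oc,
                         filter = config$filter,
                         pseudocount = config$pseudocount,
                         n_iter = config$n_iter,
                         subsample_frac = config$subsample_frac,
                         alpha = config$alpha, threshold = config$threshold,
                         n_perm = config$n_perm, seed = seeds[2] + i,
                         ties = config$ties))
    fits[[oc]] <- fit
    emit(fit$associations, paste0("associations_", oc, ".tsv"))
    if (!is.null(fit$mrs)) {
      emit(data.frame(sample_id = names(fit$mrs$score),
                      mrs = fit$mrs$score, raw = fit$mrs$raw),
           paste0("mrs_", oc, ".tsv"))
      emit(fit$km$curves, paste0("km_", oc, ".tsv"))
      summaries[[oc]] <- list(
        n_selected = sum(fit$associations$selected),
        hr_per_sd = fit$mrs_cox$hr_per_sd,
        hr_pooled_ci = if (!is.null(fit$mrs_cox$pooled)) fit$mrs_cox$pooled$ci95,
        logrank_p = fit$km$logrank_p, lrt_p = fit$km$lrt_p,
        median_survival = as.list(fit$km$medians))
    } else summaries[[oc]] <- list(n_selected = 0L)
  }
  jsonlite::write_json(summaries, file.path(config$out_dir, "mrs_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs[["mrs_summary.json"]] <- file.path(config$out_dir, "mrs_summary.json")

  ## immune stage
  if (!is.null(config$immune)) {
    imm <- as.matrix(read.delim(config$immune, row.names = 1L,
                                check.names = FALSE))
    fit_os <- fits[[config$outcomes[1]]]
    if (!is.null(fit_os$mrs)) {
      emit(stage("immune_logistic",
                 logistic_assoc(imm, fit_os$mrs, metadata)),
           "immune_logistic.tsv")
      selected <- names(coef(fit_os))
      emit(stage("immune_spearman",
                 spearman_matrix(fit_os$clr[, selected, drop = FALSE],
                                 imm[rownames(fit_os$clr), , drop = FALSE])),
           "immune_spearman.tsv")
    }
  }
  if (!is.null(config$expression) && !is.null(config$gene_sets)) {
    expr <- as.matrix(read.delim(config$expression, row.names = 1L,
                                 check.names = FALSE))
    fit_os <- fits[[config$outcomes[1]]]
    if (!is.null(fit_os$mrs)) {
      sp <- stage("expression_spearman",
                  spearman_matrix(fit_os$clr[, names(coef(fit_os)), drop = FALSE],
                                  t(expr)[rownames(fit_os$clr), , drop = FALSE]))
      emit(sp, "expression_spearman.tsv")
      hits <- unique(sp$target[!is.na(sp$p) & sp$p < 0.05])
      if (length(hits)) {
        ora <- stage("ora", hypergeom_ora(hits, rownames(expr),
                                          read_gmt(config$gene_sets)))
        emit(ora, "kegg_ora.tsv")
      }
    }
  }

  manifest <- list(package = "mrsurv",
                   version = as.character(packageVersion("mrsurv")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config_hash = fnv1a_hash(config),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
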