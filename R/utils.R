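## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_matrix <- function(x, what = "matrix", nonneg = TRUE, integer = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(what, " must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop2(what, " is empty (", nrow(x), " x ", ncol(x), ")")
  if (anyNA(x)) stop2(what, " contains missing values")
  if (nonneg && any(x < 0)) stop2(what, " contains negative values")
  if (integer && any(x != round(x)))
    stop2(what, " must contain integer counts")
  invisible(x)
}

## align a metadata data.frame to the rownames of a matrix
align_meta <- function(x, metadata, id_col = "sample_id") {
  ids <- rownames(x)
  if (is.null(ids)) stop2("matrix must carry sample rownames")
  if (!id_col %in% names(metadata))
    stop2("metadata lacks required column '", id_col, "'")
  miss <- setdiff(ids, metadata[[id_col]])
  if (length(miss))
    stop2("metadata is missing samples: ", paste(head(miss, 5), collapse = ", "))
  metadata[match(ids, metadata[[id_col]]), , drop = FALSE]
}

## 32-bit FNV-1a hash of a serialized R object; used for config fingerprints.
## Arithmetic kept in doubles < 2^53 (R has no native uint32).
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## derive a stream of sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2147483647)
  sample.int(2147483646L, n)
}

smoking_levels <- c("never", "current", "former", "not_reported")

#' Build the adjustment covariate matrix used throughout the pipeline
#'
#' Encodes the standard adjustment set: age (continuous, years), sex
#' (indicator for male), tumor stage (indicator for IIB vs I/IIA) and
#' cigarette smoking (indicators for current, former and not-reported vs
#' never). Columns not requested are omitted; extra numeric metadata columns
#' can be appended by name.
#'
#' @param metadata data.frame with columns among `age`, `sex`, `stage`,
#'   `smoking` plus any extra numeric columns named in `covariates`.
#' @param covariates character vector of covariate names to include.
#' @return numeric matrix with one row per metadata row.
#' @export
build_covariates <- function(metadata,
                             covariates = c("age", "sex", "stage", "smoking")) {
  if (length(covariates) == 0L) return(NULL)
  cols <- list()
  for (cv in covariates) {
    if (cv == "age") {
      cols[["age"]] <- as.numeric(metadata$age)
    } else if (cv == "sex") {
      cols[["sex_male"]] <- as.numeric(metadata$sex %in% c("male", "Male", "M", 1))
    } else if (cv == "stage") {
      cols[["stage_iib"]] <- as.numeric(metadata$stage %in% c("IIB", "iib", 1))
    } else if (cv == "smoking") {
      sm <- as.character(metadata$smoking)
      sm[is.na(sm)] <- "not_reported"
      sm <- factor(sm, levels = smoking_levels)
      if (anyNA(sm)) stop2("smoking values outside ", paste(smoking_levels, collapse = "/"))
      mm <- model.matrix(~sm)[, -1, drop = FALSE]
      colnames(mm) <- paste0("smoking_", smoking_levels[-1])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    } else {
      if (!cv %in% names(metadata)) stop2("unknown covariate '", cv, "'")
      cols[[cv]] <- as.numeric(metadata[[cv]])
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- metadata$sample_id
  ## drop constant columns (e.g. a smoking level absent from a subset)
  keep <- apply(out, 2L, function(z) length(unique(z)) > 1L)
  out[, keep, drop = FALSE]
}
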