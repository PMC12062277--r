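#' Dementia status from cognitive scores
#'
#' A participant is considered demented at last evaluation when the
#' Mini-Mental State Examination score is at most 24 or the Clinical Dementia
#' Rating is at least 1. Either score may be absent (`NA`); at least one must
#' be present.
#'
#' @param mmse MMSE score (0-30) or `NA`.
#' @param cdr CDR (>= 0) or `NA`.
#' @return `TRUE`/`FALSE`.
#' @export
assign_dementia <- function(mmse = NA, cdr = NA) {
  if (is.na(mmse) && is.na(cdr)) {
    abort("at least one of `mmse` and `cdr` must be present.", class = "graphomix_missing_data")
  }
  (!is.na(mmse) && mmse <= 24) || (!is.na(cdr) && cdr >= 1)
}

#' Case/control diagnosis from neuropathology and dementia status
#'
#' Combines the CERAD plaque score (0-3), Braak tau stage (0-6), and dementia
#' at last evaluation into a three-way label: controls have CERAD 0-1 and
#' Braak 0-3 without dementia, with the extra requirement that a Braak stage
#' of exactly 3 is only compatible with CERAD 0; cases have CERAD 2-3 and
#' Braak 3-6 with dementia; every other combination is excluded.
#'
#' @param cerad integer 0-3.
#' @param braak integer 0-6.
#' @param dementia logical, see [assign_dementia()].
#' @return one of `"AD"`, `"control"`, `"excluded"`.
#' @export
assign_diagnosis <- function(cerad, braak, dementia) {
  if (!cerad %in% 0:3) abort("`cerad` must be in 0..3.")
  if (!braak %in% 0:6) abort("`braak` must be in 0..6.")
  stopifnot(is.logical(dementia), length(dementia) == 1L, !is.na(dementia))
  control <- cerad %in% c(0, 1) && braak %in% 0:3 && !dementia &&
    (braak != 3 || cerad == 0)
  case <- cerad %in% c(2, 3) && braak %in% 3:6 && dementia
  if (case) "AD" else if (control) "control" else "excluded"
}

#' Log2 transform with pseudocount
#'
#' @param x numeric matrix of non-negative measurements (entries must exceed
#'   `-pseudocount`).
#' @param pseudocount value added before taking logs; defaults to 1.
#' @return matrix of `log2(x + pseudocount)`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) abort("non-finite values in input matrix.", class = "graphomix_invalid_data")
  if (any(x + pseudocount <= 0)) {
    abort("entries must exceed -pseudocount.", class = "graphomix_invalid_data")
  }
  log2(x + pseudocount)
}

#' Median-center each feature
#'
#' Subtracts the per-column median so every feature has median zero.
#'
#' @param x numeric matrix (samples x features).
#' @return centered matrix.
#' @export
median_center <- function(x) {
  x <- as.matrix(x)
  sweep(x, 2L, apply(x, 2L, median), "-")
}

#' Regress covariates out of every feature
#'
#' Fits, per feature, an ordinary least-squares model on the supplied
#' covariates plus an intercept and returns the residuals. Numeric covariates
#' enter as-is; character or factor covariates are expanded to treatment
#' contrasts. Samples with missing covariate values are excluded from the
#' fit, and their residuals are computed from the fitted coefficients with
#' missing covariates treated as the covariate mean (reference level for
#' factors), preserving the sample count.
#'
#' @param x numeric matrix (samples x features).
#' @param covariates data frame with one row per sample.
#' @return matrix of residuals with the dimensions of `x`.
#' @export
residualize_covariates <- function(x, covariates) {
  x <- as.matrix(x)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(x)) abort("covariates are not aligned to samples.")
  # drop zero-variance columns, expand factors
  keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1L, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) {
    return(sweep(x, 2L, colMeans(x), "-"))
  }
  mm_terms <- stats::model.matrix(~., data = stats::model.frame(~., covariates,
                                                                na.action = stats::na.pass))
  if (ncol(mm_terms) >= nrow(x)) abort("more covariate columns than samples.")
  qrd <- qr(mm_terms[stats::complete.cases(mm_terms), , drop = FALSE])
  if (qrd$rank < ncol(mm_terms)) {
    bad <- colnames(mm_terms)[qrd$pivot[(qrd$rank + 1):ncol(mm_terms)]]
    abort(sprintf("singular covariate design; offending column(s): %s",
                  paste(bad, collapse = ", ")),
          class = "graphomix_singular_design")
  }
  complete <- stats::complete.cases(mm_terms)
  mm_fit <- mm_terms[complete, , drop = FALSE]
  beta <- qr.coef(qr(mm_fit), x[complete, , drop = FALSE])
  # impute design for incomplete samples at the column mean
  mm_all <- mm_terms
  for (j in seq_len(ncol(mm_all))) {
    nas <- is.na(mm_all[, j])
    if (any(nas)) mm_all[nas, j] <- mean(mm_all[!nas, j])
  }
  res <- x - mm_all %*% beta
  dimnames(res) <- dimnames(x)
  res
}

#' Preprocess a feature matrix
#'
#' Applies, in order: optional log2 transform with pseudocount, per-feature
#' median centering, and optional covariate residualization.
#'
#' @param x samples x features matrix.
#' @param covariates optional data frame aligned to rows of `x`.
#' @param log2 whether the data still need a log transform (count-like
#'   inputs); set `FALSE` for already-transformed abundances.
#' @param pseudocount see [log2_transform()].
#' @return preprocessed matrix.
#' @export
preprocess_features <- function(x, covariates = NULL, log2 = TRUE, pseudocount = 1) {
  x <- as.matrix(x)
  if (log2) x <- log2_transform(x, pseudocount)
  x <- median_center(x)
  if (!is.null(covariates)) x <- residualize_covariates(x, covariates)
  x
}

# ---- delimited readers/writers ---------------------------------------------

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a feature matrix from delimited text
#'
#' Expects a header of feature symbols with the first column holding sample
#' identifiers; the delimiter (tab or comma) is sniffed from the first line.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("feature matrix contains non-finite values.",
                                class = "graphomix_invalid_data")
  rownames(m) <- ids
  m
}

#' Write a feature matrix as tab-delimited text
#' @param x matrix with sample ids as rownames.
#' @param path destination.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reserved columns (when present): `sample_id`, `label`, `cerad`, `braak`,
#' `mmse`, `cdr`, `age`, `sex`, `pmi`. Delimiter is sniffed.
#' @param path file path.
#' @return a tibble.
#' @export
read_metadata <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                              check.names = FALSE, stringsAsFactors = FALSE))
}

#' Write a cohort to a directory
#'
#' Emits one tab-delimited feature matrix per modality
#' (`features_<modality>.tsv`), a metadata table (`metadata.tsv` with the
#' label and availability masks), and each prior graph as an edge-list TSV.
#'
#' @param cohort an `omics_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$features)) {
    write_feature_matrix(cohort$features[[nm]],
                         file.path(dir, paste0("features_", nm, ".tsv")))
    if (!is.null(cohort$graphs[[nm]])) {
      write_graph_spec(as_graph_spec(cohort$graphs[[nm]], name = nm),
                       file.path(dir, paste0("graph_", nm, ".tsv")),
                       format = "edge_list_tsv")
    }
  }
  meta <- tibble(sample_id = cohort$sample_ids, label = cohort$labels)
  meta <- dplyr::left_join(meta, cohort$masks, by = "sample_id")
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(cohort$informative)) {
    writeLines(cohort$informative, file.path(dir, "informative_nodes.txt"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `features_<modality>.tsv`,
#'   `metadata.tsv`, and optionally `graph_<modality>.tsv`.
#' @return an `omics_cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  feat_files <- list.files(dir, pattern = "^features_.*\\.tsv$", full.names = TRUE)
  if (!length(feat_files)) abort("no feature matrices found.")
  modalities <- sub("^features_(.*)\\.tsv$", "\\1", basename(feat_files))
  features <- lapply(feat_files, read_feature_matrix)
  names(features) <- modalities
  graphs <- list()
  for (nm in modalities) {
    gp <- file.path(dir, paste0("graph_", nm, ".tsv"))
    if (file.exists(gp)) {
      spec <- load_graph(gp, format = "edge_list_tsv")
      graphs[[nm]] <- graph_spec_to_igraph(spec)
    }
  }
  masks <- meta[, c("sample_id", intersect(modalities, names(meta))), drop = FALSE]
  for (nm in modalities) {
    if (!nm %in% names(masks)) {
      masks[[nm]] <- masks$sample_id %in% rownames(features[[nm]])
    } else {
      masks[[nm]] <- as.logical(masks[[nm]])
    }
  }
  inf_path <- file.path(dir, "informative_nodes.txt")
  structure(list(
    sample_ids = meta$sample_id,
    labels = as.integer(meta$label),
    features = features,
    feature_ids = lapply(features, colnames),
    masks = masks,
    informative = if (file.exists(inf_path)) readLines(inf_path) else character(0),
    graphs = if (length(graphs)) graphs else NULL,
    config = NULL
  ), class = "omics_cohort")
}
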