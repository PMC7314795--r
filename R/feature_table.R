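#' radharmony: ComBat-family harmonization of radiomic feature tables
#'
#' Location-scale harmonization of multicenter feature tables with the
#' empirical-Bayes ComBat family (ComBat, M-ComBat, B-ComBat, BM-ComBat),
#' silhouette-guided discovery of harmonization labels, an evaluation
#' battery, a synthetic multicenter generator, and an imbalance-aware
#' machine-learning benchmark harness.
#'
#' The main entry point is [harmonize()], which fits the batch-effect model
#' and returns a `"radharmony"` object with the usual modelling methods
#' (`print`, `summary`, `coef`, `fitted`, `predict`, `plot`, `residuals`).
#'
#' @keywords internal
"_PACKAGE"

## ---- internal validation helpers ------------------------------------------

## values: numeric samples x features matrix with unique dimnames
check_values <- function(values, min_samples = 2L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)", call. = FALSE)
  if (nrow(values) < min_samples)
    stop(sprintf("need at least %d samples, got %d", min_samples, nrow(values)),
         call. = FALSE)
  if (ncol(values) < 1L)
    stop("need at least one feature", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains missing or non-finite entries", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  values
}

## batch: anything coercible to factor, aligned to rows of values.
## Labels are treated as opaque categories; integer-looking labels stay nominal.
check_batch <- function(batch, n, min_per_batch = 2L, warn_small = TRUE) {
  if (length(batch) != n)
    stop(sprintf("'batch' has length %d but there are %d samples",
                 length(batch), n), call. = FALSE)
  if (anyNA(batch)) stop("'batch' contains missing labels", call. = FALSE)
  batch <- factor(as.character(batch))
  tab <- table(batch)
  if (any(tab < min_per_batch))
    stop("batch(es) with fewer than ", min_per_batch, " samples: ",
         paste(names(tab)[tab < min_per_batch], collapse = ", "), call. = FALSE)
  if (warn_small && any(tab < 3L))
    warning("batch(es) with fewer than 3 samples: ",
            paste(names(tab)[tab < 3L], collapse = ", "),
            "; scale estimates will be unstable", call. = FALSE)
  batch
}

check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n)
    stop("'covariates' must have one row per sample", call. = FALSE)
  if (anyNA(covariates)) stop("'covariates' contains missing values", call. = FALSE)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (qr(covariates)$rank < ncol(covariates))
    stop("covariate matrix is rank deficient", call. = FALSE)
  covariates
}

infer_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else if (ext %in% c("tsv", "txt", "tab")) "\t"
  else stop("cannot infer delimiter from extension '.", ext,
            "' (use .csv or .tsv)", call. = FALSE)
}

#' Read a feature table from CSV/TSV
#'
#' Reads a samples-by-features table with a sample-identifier column and,
#' optionally, a batch-label column, covariate columns and a binary outcome
#' column. Every column not designated is parsed as a numeric feature;
#' column and row order are preserved. Batch labels are returned as a
#' factor of opaque categories and are never coerced to numbers.
#'
#' @param path path to a `.csv` (comma) or `.tsv` (tab) file with a header.
#' @param sample_col name of the sample-identifier column.
#' @param batch_col optional name of the batch-label column.
#' @param covariate_cols optional character vector of covariate columns.
#' @param outcome_col optional name of a binary (0/1) outcome column.
#' @param drop_incomplete drop rows with missing feature values instead of
#'   raising an error.
#' @return A list of class `"feature_table"` with components `values`
#'   (numeric matrix, sample IDs as rownames), `batch` (factor or `NULL`),
#'   `covariates` (numeric matrix or `NULL`) and `outcome` (numeric or
#'   `NULL`).
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, sample_col = "sample_id",
                               batch_col = NULL, covariate_cols = NULL,
                               outcome_col = NULL, drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- infer_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  for (col in c(sample_col, batch_col, covariate_cols, outcome_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)

  ids <- as.character(df[[sample_col]])
  if (anyDuplicated(ids))
    stop("duplicated sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  special <- c(sample_col, batch_col, covariate_cols, outcome_col)
  feat_cols <- setdiff(names(df), special)
  if (length(feat_cols) == 0L) stop("no feature columns found", call. = FALSE)

  feats <- df[feat_cols]
  for (col in feat_cols) {
    v <- feats[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in feature '%s', row %d (sample '%s')",
                     col, bad[1], ids[bad[1]]), call. = FALSE)
      feats[[col]] <- vn
    }
  }
  values <- as.matrix(feats)
  rownames(values) <- ids

  keep <- rep(TRUE, nrow(values))
  if (anyNA(values)) {
    if (!drop_incomplete)
      stop("missing feature values; set drop_incomplete = TRUE to drop those rows",
           call. = FALSE)
    keep <- stats::complete.cases(values)
    message("dropping ", sum(!keep), " incomplete row(s)")
    values <- values[keep, , drop = FALSE]
  }

  batch <- NULL
  if (!is.null(batch_col)) {
    b <- df[[batch_col]][keep]
    if (anyNA(b) || any(!nzchar(as.character(b))))
      stop("missing batch label(s) in column '", batch_col, "'", call. = FALSE)
    batch <- factor(as.character(b))
  }
  covariates <- if (!is.null(covariate_cols))
    check_covariates(as.matrix(df[keep, covariate_cols, drop = FALSE]), nrow(values))
  outcome <- if (!is.null(outcome_col)) {
    y <- df[[outcome_col]][keep]
    if (!all(y %in% c(0, 1))) stop("outcome column must be binary 0/1", call. = FALSE)
    as.numeric(y)
  }

  structure(list(values = check_values(values), batch = batch,
                 covariates = covariates, outcome = outcome),
            class = "feature_table")
}

#' Write a feature table to CSV/TSV
#'
#' Writes sample IDs first, the batch label second (when present), then all
#' features at full float precision (17 significant digits), so that a
#' read/write round trip reproduces values to within 1e-12 relative error.
#'
#' @param values numeric samples-by-features matrix, or a `"feature_table"`.
#' @param path output path; extension selects the delimiter.
#' @param batch optional per-sample batch labels.
#' @param covariates,outcome optional columns to include after the batch label.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(values, path, batch = NULL,
                                covariates = NULL, outcome = NULL) {
  if (inherits(values, "feature_table")) {
    batch <- if (is.null(batch)) values$batch else batch
    covariates <- if (is.null(covariates)) values$covariates else covariates
    outcome <- if (is.null(outcome)) values$outcome else outcome
    values <- values$values
  }
  values <- check_values(values, min_samples = 1L)
  if (!is.null(batch) && length(batch) != nrow(values))
    stop("'batch' not aligned with 'values'", call. = FALSE)
  delim <- infer_delim(path)

  out <- data.frame(sample_id = rownames(values), stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(batch)) out$batch <- as.character(batch)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    for (j in seq_len(ncol(covariates)))
      out[[colnames(covariates)[j]]] <- sprintf("%.17g", covariates[, j])
  }
  if (!is.null(outcome)) out$outcome <- outcome
  for (j in seq_len(ncol(values)))
    out[[colnames(values)[j]]] <- sprintf("%.17g", values[, j])

  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$batch)) {
    tab <- table(x$batch)
    cat("Batches:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  if (!is.null(x$covariates))
    cat("Covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$outcome))
    cat(sprintf("Outcome: %d/%d events (%.1f%%)\n", sum(x$outcome),
                length(x$outcome), 100 * mean(x$outcome)))
  invisible(x)
}
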