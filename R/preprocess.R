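#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants expected of a raw count matrix: unique gene and
#' sample identifiers, non-negative values, and (by default) integer counts.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param allow_real Allow non-integer values (for pre-normalized input).
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_counts <- function(counts, allow_real = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count %g at gene '%s', sample '%s'",
                 counts[neg[1, 1], neg[1, 2]],
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  }
  if (!allow_real) {
    ni <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(ni)) {
      stop(sprintf("non-integer count %g at gene '%s', sample '%s' (use allow_real = TRUE for pre-normalized input)",
                   counts[ni[1, 1], ni[1, 2]],
                   rownames(counts)[ni[1, 1]], colnames(counts)[ni[1, 2]]))
    }
  }
  invisible(counts)
}

#' Read a gene-level count matrix from TSV
#'
#' Expects a header row `gene_id<TAB>sample1<TAB>sample2...` followed by one
#' row per gene. Malformed input (ragged rows, duplicate ids, negative or
#' non-integer counts) raises an error naming the offending row or cell.
#'
#' @param path Path to a tab-delimited UTF-8 text file.
#' @inheritParams validate_counts
#' @return Numeric matrix of counts with gene ids as rownames.
#' @export
read_counts <- function(path, allow_real = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("counts file needs a header and at least one gene row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_head <- length(fields[[1L]])
  if (ncol_head < 2L) stop("counts header must name a gene id column and at least one sample")
  bad <- which(vapply(fields, length, 1L) != ncol_head)
  if (length(bad))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad[1L], ncol_head, length(fields[[bad[1L]]])))
  sample_ids <- fields[[1L]][-1L]
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_head - 1L))
  )
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_head - 1L)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("non-numeric count in row for gene '%s'", gene_ids[bad_row]))
  }
  dimnames(mat) <- list(gene_ids, sample_ids)
  validate_counts(mat, allow_real = allow_real)
  mat
}

#' Write a numeric matrix as a gene-id-keyed TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the identifier column (first column).
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sheet is a CSV with header `sample_id,condition,time_h,replicate`
#' describing the two-condition time-course design (conditions `control` and
#' `salt`; times in hours). When a count matrix is supplied the sample sets
#' must match exactly, and the returned sheet is ordered to the matrix
#' columns.
#'
#' @param path Path to the CSV file.
#' @param counts Optional count matrix to cross-check sample ids against.
#' @param conditions Allowed condition labels.
#' @return A data.frame with columns sample_id, condition, time_h, replicate.
#' @export
read_sample_sheet <- function(path, counts = NULL,
                              conditions = c("control", "salt")) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, counts = counts, conditions = conditions)
}

#' @rdname read_sample_sheet
#' @param sheet A data.frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL,
                                  conditions = c("control", "salt")) {
  need <- c("sample_id", "condition", "time_h", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  bad_cond <- setdiff(unique(sheet$condition), conditions)
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         " (expected ", paste(conditions, collapse = "/"), ")")
  if (!is.numeric(sheet$time_h) || anyNA(sheet$time_h))
    stop("time_h must be numeric hours")
  if (!all(sheet$replicate == round(sheet$replicate)) || any(sheet$replicate < 1))
    stop("replicate must be a positive integer")
  key <- paste(sheet$condition, sheet$time_h, sheet$replicate)
  if (anyDuplicated(key))
    stop("duplicated (condition, time_h, replicate) triple: ",
         key[duplicated(key)][1L])
  if (!is.null(counts)) {
    missing_in_sheet <- setdiff(colnames(counts), sheet$sample_id)
    extra_in_sheet <- setdiff(sheet$sample_id, colnames(counts))
    if (length(missing_in_sheet) || length(extra_in_sheet))
      stop("sample sheet does not match count matrix columns;",
           if (length(missing_in_sheet))
             paste0(" missing from sheet: ", paste(missing_in_sheet, collapse = ", ")),
           if (length(extra_in_sheet))
             paste0(" absent from counts: ", paste(extra_in_sheet, collapse = ", ")))
    sheet <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
    rownames(sheet) <- NULL
  }
  sheet
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each usable gene (strictly positive
#' geometric mean across samples, i.e. no zero count) form the ratio of its
#' count to its geometric mean; the size factor of a sample is the median of
#' these ratios.
#'
#' @param counts Validated count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts, allow_real = TRUE)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene has strictly positive counts in every sample; ",
         "add a pseudo-count or filter samples before normalization")
  ratios <- counts[usable, , drop = FALSE] / exp(log_geo[usable])
  s <- apply(ratios, 2L, stats::median)
  if (any(s <= 0)) stop("non-positive size factor estimated")
  s
}

#' Variance-stabilizing log transform
#'
#' Divides counts by their sample size factors and applies `log2(x + 1)`,
#' a dependency-free stabilized transform whose downstream use here is only
#' through gene-gene correlations.
#'
#' @param counts Count matrix (genes x samples).
#' @param size_factors Positive per-sample factors, as from
#'   [estimate_size_factors()]. Defaults to estimating them from `counts`.
#' @return Matrix of transformed expression values, same dimnames as input.
#' @export
vst_transform <- function(counts, size_factors = estimate_size_factors(counts)) {
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per sample")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, size_factors, `/`) + 1)
}

#' Keep only high-variance genes
#'
#' Computes each gene's sample variance across all samples and retains genes
#' whose variance is at or above the given percentile of the per-gene
#' variance distribution (type-7 linear-interpolation quantile). Gene order
#' is preserved.
#'
#' @param x Expression matrix (genes x samples).
#' @param percentile Percentile cutoff in `[0, 100)`; 95 keeps roughly the
#'   top 5\% most variable genes.
#' @return The row-subset expression matrix.
#' @export
filter_by_variance <- function(x, percentile = 95) {
  if (ncol(x) < 2L) stop("variance filtering needs at least two samples")
  if (!is.numeric(percentile) || percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  v <- row_variances(x)
  cutoff <- stats::quantile(v, probs = percentile / 100, type = 7, names = FALSE)
  x[v >= cutoff, , drop = FALSE]
}

#' Per-gene sample variance
#'
#' @param x Numeric matrix; variance is taken across columns for each row.
#' @return Named numeric vector of variances.
#' @export
row_variances <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}
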