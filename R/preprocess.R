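# Readers, writers and normalization for gene-by-sample matrices and
# clinical tables. Matrices are plain numeric matrices with gene ids as
# rownames and sample ids as colnames; sample class (tumor/normal) travels
# separately as a named character vector from the sample sheet.

#' Read a gene-by-sample expression or copy-number matrix
#'
#' Expects tab-separated text with a first column named `gene_id` and one
#' column per sample; `NA` marks missing values, `.` is the decimal mark.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes as rows (rownames = gene ids), samples as
#'   columns (colnames = sample ids).
#' @export
read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "gene_id")) {
    stop("expression TSV must have a first column named 'gene_id': ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$gene_id)
  m
}

#' Write a gene-by-sample matrix in the package TSV dialect
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet assigning each sample to the tumor or normal class
#'
#' @param path TSV with columns `sample_id` and `class` (values `tumor` or
#'   `normal`). Class is never inferred from sample names.
#' @return Named character vector: names are sample ids, values the class.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% colnames(df))) {
    stop("sample sheet needs columns 'sample_id' and 'class': ", path)
  }
  bad <- setdiff(unique(df$class), c("tumor", "normal"))
  if (length(bad)) stop("unknown sample class(es): ", paste(bad, collapse = ", "))
  stats::setNames(df$class, df$sample_id)
}

#' Read a clinical table
#'
#' @param path TSV with columns `sample_id`, `time_years`, `event`, `grade`
#'   and then any covariate columns. `time_years` must be non-negative,
#'   `event` in 0/1, `grade` in 1/2/3 or NA.
#' @return A data.frame with those columns, covariates preserved.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_years", "event", "grade")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "), " in ", path)
  if (any(df$time_years < 0, na.rm = TRUE)) stop("negative survival time in ", path)
  if (!all(df$event %in% c(0L, 1L, NA))) stop("event must be 0/1 in ", path)
  if (!all(df$grade %in% c(1L, 2L, 3L, NA))) stop("grade must be 1, 2 or 3 in ", path)
  df
}

#' Quantile-normalize the samples of an expression matrix
#'
#' Every sample (column) is mapped onto the common reference distribution
#' given by the row-wise mean of the sorted columns; ties share the mean of
#' the reference values spanning their rank range (midrank convention).
#'
#' @param m Numeric matrix, genes x samples, at least two samples.
#' @return Matrix of the same shape; after normalization the sorted values
#'   of every column are identical.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) stop("quantile normalization undefined for a single sample")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Aggregate probe-level rows to the gene level
#'
#' Probes with no mapping are dropped; each gene's value is the chosen
#' summary (default mean) of its probes' rows, computed per sample.
#'
#' @param m Numeric matrix, probes x samples (rownames = probe ids).
#' @param probe_to_gene Named character vector mapping probe id -> gene
#'   symbol; each probe maps to at most one gene.
#' @param stat Aggregation statistic: `"mean"` (default), `"median"` or
#'   `"max"`.
#' @return Numeric matrix, genes x samples, one row per mapped gene, rows in
#'   order of first appearance of each gene among the mapped probes.
#' @export
aggregate_probes <- function(m, probe_to_gene, stat = c("mean", "median", "max")) {
  stat <- match.arg(stat)
  probe_to_gene <- probe_to_gene[!is.na(probe_to_gene)]
  keep <- intersect(rownames(m), names(probe_to_gene))
  if (length(keep) == 0L) {
    warning("probe-to-gene mapping matches no rows; returning empty matrix")
    out <- m[0, , drop = FALSE]
    return(out)
  }
  m <- m[keep, , drop = FALSE]
  gene <- factor(probe_to_gene[keep], levels = unique(probe_to_gene[keep]))
  fun <- switch(stat, mean = mean, median = stats::median, max = max)
  out <- do.call(rbind, lapply(split(seq_along(gene), gene), function(idx) {
    apply(m[idx, , drop = FALSE], 2, fun)
  }))
  rownames(out) <- levels(gene)
  colnames(out) <- colnames(m)
  out
}

#' Log-transform and median-center an expression matrix
#'
#' Computes `log2(value + pseudocount)` and subtracts the per-gene (or
#' per-sample) median.
#'
#' @param m Non-negative numeric matrix, genes x samples.
#' @param pseudocount Added before the log; default 1.
#' @param center Centering axis, `"gene"` (default) or `"sample"`.
#' @return Matrix of the same shape, log2 scale, medians zero along the
#'   centering axis.
#' @export
log_median_center <- function(m, pseudocount = 1, center = c("gene", "sample")) {
  center <- match.arg(center)
  if (any(m < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  lg <- log2(m + pseudocount)
  if (center == "gene") {
    lg - apply(lg, 1, stats::median, na.rm = TRUE)
  } else {
    sweep(lg, 2, apply(lg, 2, stats::median, na.rm = TRUE))
  }
}

#' Collapse probe-level copy-number values to the gene level
#'
#' The gene-level value is the mean of the probes covering the gene
#' (the aggregation statistic is fixed at the mean for copy number).
#'
#' @inheritParams aggregate_probes
#' @return Numeric matrix, genes x samples.
#' @export
cnv_gene_level <- function(m, probe_to_gene) {
  aggregate_probes(m, probe_to_gene, stat = "mean")
}
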