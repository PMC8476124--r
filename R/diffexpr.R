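#' Median-of-ratios size-factor normalization
#'
#' Computes per-sample size factors as the median, over genes with nonzero
#' counts in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples, and divides each column by its factor.
#' This is the classical count-normalization scheme of DESeq-style
#' differential expression; the downstream de-repression statistic consumes
#' only the resulting log2-fold changes.
#'
#' @param counts non-negative matrix or data.frame, genes x samples, with
#'   gene ids as row names.
#' @return list with `size_factors` (named numeric) and `normalized`
#'   (numeric matrix).
#' @export
median_ratio_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; consider a ",
         "pseudo-reference fallback or filtering samples")
  }
  ref <- exp(log_geo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(col / ref)
  })
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Per-gene log2-fold changes from a normalized matrix
#'
#' `log2fc = log2((mean_treatment + pc) / (mean_control + pc))`, with a
#' pseudocount making the ratio finite for genes with zero counts in one
#' condition. `mean_expr` is the mean normalized count over all samples and
#' feeds the expression filter.
#'
#' @param normalized numeric matrix, genes x samples (see
#'   [median_ratio_normalize()]).
#' @param conditions data.frame with `sample`, `condition`; sample names
#'   must match the matrix columns.
#' @param treatment,control condition labels to contrast.
#' @param pseudocount added to both condition means (default 0.5).
#' @return data.frame (fold-change table): `gene_id`, `log2fc`, `mean_expr`,
#'   `expressed` (initialized `TRUE`; see [filter_expressed()]).
#' @export
estimate_log2fc <- function(normalized, conditions,
                            treatment = "treatment", control = "control",
                            pseudocount = 0.5) {
  normalized <- as.matrix(normalized)
  if (any(normalized < 0)) stop("negative counts in normalized matrix")
  cond <- conditions$condition[match(colnames(normalized), conditions$sample)]
  if (anyNA(cond)) {
    stop("samples missing from the condition table: ",
         paste(colnames(normalized)[is.na(cond)], collapse = ", "))
  }
  if (sum(cond == treatment) < 1 || sum(cond == control) < 1) {
    stop("both conditions need at least one sample")
  }
  m_trt <- rowMeans(normalized[, cond == treatment, drop = FALSE])
  m_ctl <- rowMeans(normalized[, cond == control, drop = FALSE])
  data.frame(
    gene_id = rownames(normalized),
    log2fc = log2((m_trt + pseudocount) / (m_ctl + pseudocount)),
    mean_expr = rowMeans(normalized),
    expressed = TRUE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Flag expressed genes by mean normalized count
#'
#' Sets `expressed <- mean_expr >= min_mean`; downstream de-repression
#' statistics only see expressed genes.
#'
#' @param fc fold-change table (see [estimate_log2fc()]).
#' @param min_mean expression threshold on mean normalized counts
#'   (default 10).
#' @return the table with `expressed` set.
#' @export
filter_expressed <- function(fc, min_mean = 10) {
  fc$expressed <- fc$mean_expr >= min_mean
  fc
}

#' Ingest an externally computed fold-change table
#'
#' Reads a TSV with `gene_id`, `log2fc`, `mean_expr` (for example DESeq2
#' output exported with those columns) and passes the values through
#' verbatim — no re-normalization or shrinkage is applied, so externally
#' computed statistics are preserved exactly.
#'
#' @param path TSV path.
#' @return fold-change table data.frame with `expressed` initialized `TRUE`
#'   if absent.
#' @export
read_fold_changes <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "log2fc", "mean_expr")
  if (!all(need %in% names(df))) {
    stop("fold-change table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"expressed" %in% names(df)) df$expressed <- TRUE
  df
}
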