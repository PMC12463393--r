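#' Quality-control cell filter
#'
#' Removes cells with an unusually high number of UMIs (total UMI >=
#' `qc_max_umi`, default 8000) or high mitochondrial content (mito
#' percent >= `qc_max_mito_pct`, default 15). Both bounds are inclusive
#' on the removal side: a cell is retained only if it is strictly below
#' both. Cell order is preserved and the number removed per criterion is
#' reported via `message()` and in `metadata(x)$qc_log`.
#'
#' @param x an [ExpressionDataset-class] with derived QC fields.
#' @param cfg an [analysisConfig()].
#' @return the filtered [ExpressionDataset-class].
#' @name qcFilter
#' @export
setMethod("qcFilter", "ExpressionDataset", function(x,
                                                    cfg = analysisConfig()) {
  umi_bad <- totalUMI(x) >= cfg$qc_max_umi
  mito_bad <- mitoPercent(x) >= cfg$qc_max_mito_pct
  keep <- !umi_bad & !mito_bad
  if (!any(keep))
    stop("QC removed every cell; downstream stages are undefined")
  message(sprintf("qcFilter: removed %d cells (%d UMI >= %g, %d mito >= %g%%), kept %d",
                  sum(!keep), sum(umi_bad), cfg$qc_max_umi, sum(mito_bad),
                  cfg$qc_max_mito_pct, sum(keep)))
  out <- x[, keep]
  S4Vectors::metadata(out)$qc_log <- list(
    n_removed = sum(!keep), n_umi = sum(umi_bad), n_mito = sum(mito_bad),
    n_kept = sum(keep))
  out
})

#' Library-size normalization (counts per 10k, log1p)
#'
#' Adds a `"logcounts"` assay: each cell's counts scaled to a total of
#' 10,000 and transformed with `log(1 + x)`. Raw counts are retained; the
#' transform is always recomputed from the raw layer, so applying it
#' twice equals applying it once.
#'
#' @param x an [ExpressionDataset-class].
#' @return `x` with a `"logcounts"` assay.
#' @name normalizeLog1p
#' @export
setMethod("normalizeLog1p", "ExpressionDataset", function(x) {
  cts <- SummarizedExperiment::assay(x, "counts")
  total <- Matrix::colSums(cts)
  if (any(total == 0))
    stop("zero-total cell (should have failed QC): ",
         colnames(cts)[which(total == 0)[1L]])
  scaled <- cts %*% Matrix::Diagonal(x = 1e4 / total)
  lg <- log1p(scaled)
  dimnames(lg) <- dimnames(cts)
  SummarizedExperiment::assay(x, "logcounts") <- lg
  x
})

# fetch logcounts, computing them on the fly if absent
.logcounts <- function(x) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
    x <- normalizeLog1p(x)
  SummarizedExperiment::assay(x, "logcounts")
}
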