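#' @name accessors
#' @title Accessors for ExpressionDataset annotation
#' @description Column- and row-annotation accessors: group labels, cell
#'   types, per-cell total UMI and mitochondrial percent, and the
#'   mitochondrial / transcription-factor gene flags.
#' @param x an [ExpressionDataset-class]
#' @return vectors parallel to cells (or genes for `isMito`/`isTF`).
NULL

#' @rdname accessors
#' @export
setGeneric("cellGroups", function(x) standardGeneric("cellGroups"))
#' @rdname accessors
#' @export
setMethod("cellGroups", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$group)

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setMethod("cellTypes", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$cell_type)

#' @rdname accessors
#' @export
setGeneric("totalUMI", function(x) standardGeneric("totalUMI"))
#' @rdname accessors
#' @export
setMethod("totalUMI", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$total_umi)

#' @rdname accessors
#' @export
setGeneric("mitoPercent", function(x) standardGeneric("mitoPercent"))
#' @rdname accessors
#' @export
setMethod("mitoPercent", "ExpressionDataset", function(x)
  SummarizedExperiment::colData(x)$mito_pct)

#' @rdname accessors
#' @export
setGeneric("isMito", function(x) standardGeneric("isMito"))
#' @rdname accessors
#' @export
setMethod("isMito", "ExpressionDataset", function(x)
  SummarizedExperiment::rowData(x)$is_mito)

#' @rdname accessors
#' @export
setGeneric("isTF", function(x) standardGeneric("isTF"))
#' @rdname accessors
#' @export
setMethod("isTF", "ExpressionDataset", function(x)
  SummarizedExperiment::rowData(x)$is_tf)

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "ExpressionDataset", function(x)
  SummarizedExperiment::rowData(x)$symbol)

#' @rdname qcFilter
#' @export
setGeneric("qcFilter", function(x, cfg = analysisConfig())
  standardGeneric("qcFilter"))

#' @rdname normalizeLog1p
#' @export
setGeneric("normalizeLog1p", function(x) standardGeneric("normalizeLog1p"))

#' @rdname scoreFraction
#' @export
setGeneric("scoreFraction", function(x, set, ...)
  standardGeneric("scoreFraction"))
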