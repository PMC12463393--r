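#' @import methods
#' @importFrom stats p.adjust pchisq pnorm pt sd mad density var predict
#'   rnorm rpois rnbinom runif fivenum cor setNames lm
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

VALID_GROUPS <- c("Y", "O", "O.T")

#' ExpressionDataset: single-nucleus counts with QC and annotation
#'
#' An S4 container extending
#' [SingleCellExperiment::SingleCellExperiment] for cell x gene count data
#' from a three-group (Y / O / O.T) hypothalamus study design. Rows are
#' genes, columns are cells. The `"counts"` assay holds raw non-negative
#' integer counts; [normalizeLog1p()] adds a `"logcounts"` assay.
#' `colData` carries `cell_id`, `group` (one of Y, O, O.T), `cell_type`,
#' and the derived QC fields `total_umi` (per-cell count sum) and
#' `mito_pct` (percent of counts in mitochondrial genes, 0-100).
#' `rowData` carries `symbol` (unique), `is_mito` and `is_tf` flags.
#'
#' @aliases ExpressionDataset-class
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SingleCellExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  need_rd <- c("symbol", "is_mito", "is_tf")
  need_cd <- c("cell_id", "group", "cell_type", "total_umi", "mito_pct")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(rd$symbol))
    msg <- c(msg, sprintf("duplicated gene symbol: %s",
                          rd$symbol[duplicated(rd$symbol)][1L]))
  if (!all(cd$group %in% VALID_GROUPS))
    msg <- c(msg, sprintf("group labels must be in {%s}",
                          paste(VALID_GROUPS, collapse = ", ")))
  cts <- SummarizedExperiment::assay(object, "counts")
  if (length(cts) && min(cts) < 0)
    msg <- c(msg, "counts must be non-negative")
  if (any(cd$mito_pct < 0 | cd$mito_pct > 100))
    msg <- c(msg, "mito_pct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' Builds the dataset from a genes x cells count matrix plus cell and gene
#' annotation, deriving the per-cell QC fields (`total_umi`, `mito_pct`)
#' from the counts.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts; rownames are gene symbols, colnames are cell ids.
#' @param cellData data.frame with columns `cell_id`, `group`, `cell_type`
#'   (one row per cell, in column order of `counts`).
#' @param geneData data.frame with columns `symbol`, `is_mito`, `is_tf`
#'   (one row per gene, in row order of `counts`).
#' @return An [ExpressionDataset-class] object.
#' @export
ExpressionDataset <- function(counts, cellData, geneData) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (nrow(counts) != nrow(geneData))
    stop("geneData rows (", nrow(geneData), ") != matrix genes (",
         nrow(counts), ")")
  if (ncol(counts) != nrow(cellData))
    stop("cellData rows (", nrow(cellData), ") != matrix cells (",
         ncol(counts), ")")
  bad <- counts@x[counts@x < 0 | counts@x != round(counts@x)]
  if (length(bad))
    stop("counts must be non-negative integers; offending value: ", bad[1L])
  rownames(counts) <- geneData$symbol
  colnames(counts) <- cellData$cell_id
  total <- Matrix::colSums(counts)
  mito <- geneData$is_mito
  mito_counts <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_pct <- ifelse(total > 0, 100 * mito_counts / total, 0)
  cd <- S4Vectors::DataFrame(cell_id = as.character(cellData$cell_id),
                             group = as.character(cellData$group),
                             cell_type = as.character(cellData$cell_type),
                             total_umi = as.numeric(total),
                             mito_pct = as.numeric(mito_pct),
                             row.names = as.character(cellData$cell_id))
  rd <- S4Vectors::DataFrame(symbol = as.character(geneData$symbol),
                             is_mito = as.logical(geneData$is_mito),
                             is_tf = as.logical(geneData$is_tf),
                             row.names = as.character(geneData$symbol))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  methods::new("ExpressionDataset", sce)
}

#' @describeIn ExpressionDataset Compact display with group breakdown.
#' @param object an `ExpressionDataset`
#' @export
setMethod("show", "ExpressionDataset", function(object) {
  methods::callNextMethod()
  tab <- table(cellGroups(object))
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

#' GeneSetCollection: an ordered, named collection of gene sets
#'
#' Holds named gene lists (pathways, signatures) with a free-text source
#' tag per set (e.g. Hallmark, KEGG, GO, MitoCarta, custom). Set names are
#' unique; members within a set are unique and non-empty.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot source named character vector of source tags (same names).
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", source = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(lengths(object@sets) == 0))
      msg <- c(msg, "gene sets must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
      msg <- c(msg, "gene sets must not contain duplicate members")
  }
  if (length(msg)) msg else TRUE
})

#' @param sets named list of character vectors.
#' @param source character scalar or vector of source tags.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets = list(), source = "custom") {
  source <- rep_len(source, length(sets))
  names(source) <- names(sets)
  methods::new("GeneSetCollection", sets = sets, source = source)
}

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @param i set name or index
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @rdname GeneSetCollection-class
#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    shown <- utils::head(names(object@sets), 5)
    cat(" ", paste(sprintf("%s(%d)", shown, lengths(object@sets)[shown]),
                   collapse = " "), "\n")
  }
})

#' geneSets: extract the member lists of a collection
#' @param x a `GeneSetCollection`
#' @return named list of character vectors.
#' @export
geneSets <- function(x) x@sets

#' SignaturePair: opposing c1-up / c4-up gene signatures
#'
#' The pair of up-signatures derived by intersecting unique quarter
#' markers across several pathway partitions: `c1Up` tracks the program
#' enriched in the highest-scoring quarter (metabolic in the aging
#' setting), `c4Up` the opposing program of the lowest quarter (synaptic).
#' The two lists are disjoint by construction. `provenance` records the
#' pathways intersected and per-pathway marker counts.
#'
#' @slot c1Up character vector of gene symbols.
#' @slot c4Up character vector of gene symbols.
#' @slot provenance list of derivation metadata.
#' @aliases SignaturePair-class
#' @exportClass SignaturePair
setClass("SignaturePair",
         representation(c1Up = "character", c4Up = "character",
                        provenance = "list"))

setValidity("SignaturePair", function(object) {
  if (length(intersect(object@c1Up, object@c4Up)))
    "c1Up and c4Up must be disjoint" else TRUE
})

#' @param c1Up,c4Up character vectors of gene symbols.
#' @param provenance list of derivation metadata.
#' @rdname SignaturePair-class
#' @export
SignaturePair <- function(c1Up, c4Up, provenance = list()) {
  methods::new("SignaturePair", c1Up = unique(as.character(c1Up)),
               c4Up = unique(as.character(c4Up)), provenance = provenance)
}

#' @rdname SignaturePair-class
#' @export
setMethod("show", "SignaturePair", function(object) {
  cat("SignaturePair: c1-up (", length(object@c1Up), " genes), c4-up (",
      length(object@c4Up), " genes)\n", sep = "")
})

#' @rdname SignaturePair-class
#' @param x a `SignaturePair`
#' @export
c1Up <- function(x) x@c1Up

#' @rdname SignaturePair-class
#' @export
c4Up <- function(x) x@c4Up

#' SubtypeAssignment: supervised subtype membership among neurons
#'
#' Result of [assignSubtypes()]: per catalog subtype, the neuron cells
#' with raw count > 0 for the defining gene. A cell may belong to several
#' subtypes. Also carries the neuron universe and its group labels so
#' proportion and ranking operations need no re-derivation.
#'
#' @slot members named list of character vectors of cell ids.
#' @slot category named character, `"peptide"` or `"receptor"` per subtype.
#' @slot definingGene named character, defining gene symbol per subtype.
#' @slot neuronIds character, all neuron cell ids.
#' @slot neuronGroups named character, group label per neuron cell id.
#' @aliases SubtypeAssignment-class
#' @exportClass SubtypeAssignment
setClass("SubtypeAssignment",
         representation(members = "list", category = "character",
                        definingGene = "character", neuronIds = "character",
                        neuronGroups = "character"))

#' @rdname SubtypeAssignment-class
#' @param object a `SubtypeAssignment`
#' @export
setMethod("show", "SubtypeAssignment", function(object) {
  cat("SubtypeAssignment:", length(object@members), "subtypes over",
      length(object@neuronIds), "neurons\n")
  cat("  peptide:", sum(object@category == "peptide"),
      " receptor:", sum(object@category == "receptor"), "\n")
})

#' @rdname SubtypeAssignment-class
#' @param x a `SubtypeAssignment`
#' @export
setMethod("length", "SubtypeAssignment", function(x) length(x@members))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("names", "SubtypeAssignment", function(x) names(x@members))

#' subtypeMembers: member cell ids of a subtype assignment
#' @param x a `SubtypeAssignment`
#' @param subtype optional subtype name; if missing the full list.
#' @return character vector (or named list) of cell ids.
#' @export
subtypeMembers <- function(x, subtype) {
  if (missing(subtype)) x@members else x@members[[subtype]]
}
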