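#' Read a cell x gene MatrixMarket count dataset
#'
#' Reads the on-disk triplet (MatrixMarket sparse counts stored cells x
#' genes, a `genes.tsv` with columns `symbol`, `is_mito`, `is_tf`, and a
#' `cells.tsv` with columns `cell_id`, `group`, `cell_type`) into an
#' [ExpressionDataset-class] with derived QC fields. Counts are
#' transposed to the genes x cells orientation used internally.
#'
#' @param mtxPath path to the `.mtx` file (cells x genes).
#' @param genesPath path to `genes.tsv`.
#' @param cellsPath path to `cells.tsv`.
#' @return an [ExpressionDataset-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(mtxPath, genesPath, cellsPath) {
  for (p in c(mtxPath, genesPath, cellsPath))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(mtxPath)
  genes <- read.delim(genesPath, stringsAsFactors = FALSE)
  cells <- read.delim(cellsPath, stringsAsFactors = FALSE)
  if (nrow(genes) != ncol(m))
    stop("genes.tsv rows (", nrow(genes), ") != matrix gene columns (",
         ncol(m), ")")
  if (nrow(cells) != nrow(m))
    stop("cells.tsv rows (", nrow(cells), ") != matrix cell rows (",
         nrow(m), ")")
  if (anyDuplicated(genes$symbol))
    stop("duplicated gene symbol in genes.tsv: ",
         genes$symbol[duplicated(genes$symbol)][1L])
  genes$is_mito <- .asFlag(genes$is_mito)
  genes$is_tf <- .asFlag(genes$is_tf)
  ExpressionDataset(Matrix::t(m), cells, genes)
}

.asFlag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write an ExpressionDataset to MatrixMarket + TSV
#'
#' Inverse of [readCounts()]: writes `matrix.mtx` (cells x genes),
#' `genes.tsv` and `cells.tsv` under `dir`. Round-trips losslessly.
#'
#' @param d an [ExpressionDataset-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeCounts <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  cts <- SummarizedExperiment::assay(d, "counts")
  Matrix::writeMM(methods::as(Matrix::t(cts), "generalMatrix"), paths[1L])
  rd <- SummarizedExperiment::rowData(d)
  cd <- SummarizedExperiment::colData(d)
  write.table(data.frame(symbol = rd$symbol, is_mito = rd$is_mito,
                         is_tf = rd$is_tf),
              paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = cd$cell_id, group = cd$group,
                         cell_type = cd$cell_type),
              paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Parses the standard GMT dialect (name TAB description TAB members...).
#' Duplicate members within a set are dropped with a warning; lines with
#' an empty member list are rejected with a warning. Sets keep file
#' order.
#'
#' @param gmtPath path to the GMT file.
#' @param source source tag stored per set (default `"gmt"`).
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(gmtPath, source = "gmt") {
  if (!file.exists(gmtPath)) stop("file not found: ", gmtPath)
  if (length(readLines(gmtPath, n = 1L)) == 0)
    return(GeneSetCollection())
  sets <- fgsea::gmtPathways(gmtPath)
  if (anyDuplicated(names(sets)))
    stop("duplicated set name in GMT: ",
         names(sets)[duplicated(names(sets))][1L])
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping GMT line(s) with empty member list: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("dropping duplicate members within set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  GeneSetCollection(sets, source = source)
}

#' Write gene sets (or a SignaturePair) as GMT
#'
#' @param x a [GeneSetCollection-class] or [SignaturePair-class] (written
#'   as the two sets `c1_up_signature` and `c4_up_signature`).
#' @param path output GMT path.
#' @param description description field per line.
#' @return invisibly, `path`.
#' @export
writeGeneSets <- function(x, path, description = "hypoScreen") {
  if (methods::is(x, "SignaturePair"))
    x <- GeneSetCollection(list(c1_up_signature = x@c1Up,
                                c4_up_signature = x@c4Up),
                           source = "signature")
  lines <- vapply(names(x@sets), function(nm)
    paste(c(nm, description, x@sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a subtype catalog
#'
#' TSV with columns `subtype`, `gene`, `category` where category is
#' `"peptide"` (neuropeptide/hormone-secreting) or `"receptor"`.
#' Subtype names must be unique.
#'
#' @param path TSV path.
#' @return data.frame with the three validated columns.
#' @export
readSubtypeCatalog <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  validateSubtypeCatalog(cat)
}

#' @rdname readSubtypeCatalog
#' @param cat a data.frame to validate in place of a file.
#' @export
validateSubtypeCatalog <- function(cat) {
  need <- c("subtype", "gene", "category")
  if (!all(need %in% colnames(cat)))
    stop("subtype catalog needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cat$subtype))
    stop("duplicated subtype name: ",
         cat$subtype[duplicated(cat$subtype)][1L])
  bad <- setdiff(unique(cat$category), c("peptide", "receptor"))
  if (length(bad))
    stop("invalid category: ", paste(bad, collapse = ", "))
  cat[, need]
}

#' Read TF regulons
#'
#' TSV with columns `tf`, `target`, `weight` (signed real, typically +1 /
#' -1 for activation / repression).
#'
#' @param path TSV path.
#' @return data.frame(tf, target, weight).
#' @export
readRegulons <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "weight")
  if (!all(need %in% colnames(reg)))
    stop("regulon table needs columns: ", paste(need, collapse = ", "))
  reg$weight <- as.numeric(reg$weight)
  reg[, need]
}

#' Read / write GWAS summary statistics
#'
#' TSV with columns `snp`, `effect_allele`, `other_allele`, `beta`, `se`,
#' `pval`, `eaf`, `n`. Validated: unique SNP ids, `se > 0`, alleles in
#' {A,C,G,T}, `pval` in (0, 1], `eaf` in (0, 1).
#'
#' @param path TSV path.
#' @return data.frame of the validated columns.
#' @export
readGwas <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  validateGwas(g)
}

#' @rdname readGwas
#' @param g a data.frame to validate in place of a file.
#' @export
validateGwas <- function(g) {
  need <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval",
            "eaf", "n")
  if (!all(need %in% colnames(g)))
    stop("GWAS table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$snp))
    stop("duplicated SNP id: ", g$snp[duplicated(g$snp)][1L])
  if (any(g$se <= 0)) stop("se must be > 0 (SNP ",
                           g$snp[which(g$se <= 0)[1L]], ")")
  ok <- c("A", "C", "G", "T")
  if (!all(g$effect_allele %in% ok & g$other_allele %in% ok))
    stop("alleles must be in {A,C,G,T}")
  if (any(g$pval <= 0 | g$pval > 1)) stop("pval must lie in (0, 1]")
  if (any(g$eaf <= 0 | g$eaf >= 1)) stop("eaf must lie in (0, 1)")
  g[, need]
}

#' @rdname readGwas
#' @export
writeGwas <- function(g, path) {
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
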