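#' Equal-count quartile partition of cells by a pathway score
#'
#' Cells are sorted by score descending (ties broken by cell id for a
#' stable, reproducible order) and split into four contiguous blocks of
#' near-equal size: block sizes differ by at most one, with the larger
#' blocks first. `c1` is the highest-scoring quarter and `c4` the
#' lowest. The five-number summary (minimum, hinges, median, maximum) of
#' the scores is attached as the `"fivenum"` attribute for reference:
#' equal-count splitting is used because hinge-based interval assignment
#' cannot guarantee equal cell numbers under ties.
#'
#' @param scores named numeric vector of per-cell scores (names = cell
#'   ids).
#' @return named factor with levels `c1..c4`, attribute `"fivenum"`.
#' @export
quartilePartition <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 cells")
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  ord <- order(-scores, names(scores))
  n <- length(scores)
  sizes <- rep(n %/% 4, 4) + (seq_len(4) <= n %% 4)
  lab <- rep(paste0("c", 1:4), sizes)
  out <- factor(character(n), levels = paste0("c", 1:4))
  out[ord] <- lab
  names(out) <- names(scores)
  attr(out, "fivenum") <- fivenum(scores)
  out
}

#' Weighted per-group cell proportions of each quarter
#'
#' For labels computed on the pooled neuron population, the proportion
#' of group `g` in quarter `q` is the number of `g` cells in `q` divided
#' by `g`'s total cell count, so each group's four proportions sum to 1.
#'
#' @param labels factor from [quartilePartition()] (named by cell id).
#' @param groups named group label per cell.
#' @return groups x quarters matrix of proportions (rows sum to 1).
#' @export
quarterGroupProportions <- function(labels, groups) {
  if (!is.null(names(groups))) groups <- groups[names(labels)]
  tab <- table(group = groups, quarter = labels)
  prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  prop
}

#' Unique positive markers of each quarter
#'
#' One-vs-rest Wilcoxon rank-sum test on the normalized layer for each
#' quarter, keeping positive markers that pass the expression-fraction
#' (`deg_min_pct`), fold-change (`deg_logfc`, Seurat-style) and
#' BH-adjusted p (`marker_padj`) thresholds. Genes significant in more
#' than one quarter are then removed from all quarters, leaving
#' "unique" markers only.
#'
#' @param d an [ExpressionDataset-class] (or any cell subset of one).
#' @param labels factor from [quartilePartition()] over the cells of
#'   `d`.
#' @param cfg an [analysisConfig()].
#' @return data.frame(quarter, gene, avg_logFC, pct_in, pct_out, auc, p,
#'   p_adj).
#' @export
quarterUniqueMarkers <- function(d, labels, cfg = analysisConfig()) {
  if (min(table(labels)) < 3) stop("every quarter needs >= 3 cells")
  lg <- .logcounts(d)[, names(labels), drop = FALSE]
  stats <- .rankSumMulti(lg, labels)
  tabs <- lapply(levels(labels), function(q) {
    maskIn <- labels == q
    pct_in <- Matrix::rowMeans(lg[, maskIn, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(lg[, !maskIn, drop = FALSE] > 0)
    lfc <- .avgLogFC(lg, maskIn)
    st <- stats[[q]]
    keep <- pmax(pct_in, pct_out) >= cfg$deg_min_pct & lfc >= cfg$deg_logfc
    st <- st[keep, , drop = FALSE]
    st$p_adj <- p.adjust(st$p, "BH")
    st <- st[st$p_adj < cfg$marker_padj & st$auc > 0.5, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    data.frame(quarter = q, gene = st$gene,
               avg_logFC = lfc[match(st$gene, rownames(lg))],
               pct_in = pct_in[match(st$gene, rownames(lg))],
               pct_out = pct_out[match(st$gene, rownames(lg))],
               auc = st$auc, p = st$p, p_adj = st$p_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  if (is.null(out))
    return(data.frame(quarter = character(), gene = character()))
  multi <- unique(out$gene[duplicated(out$gene)])
  out <- out[!out$gene %in% multi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect unique quarter markers across pathway partitions
#'
#' The genes that are unique markers of the given quarter in every
#' supplied partition. An empty intersection is a valid result (the c2
#' and c3 quarters typically have none).
#'
#' @param tables list of marker tables from [quarterUniqueMarkers()],
#'   one per pathway partition.
#' @param quarter quarter label (`"c1"`..`"c4"`).
#' @return character vector of gene symbols.
#' @export
intersectQuarterMarkers <- function(tables, quarter) {
  if (length(tables) < 2) stop("need >= 2 pathway partitions")
  Reduce(intersect, lapply(tables, function(t)
    t$gene[t$quarter == quarter]))
}

#' Derive the opposing c1-up / c4-up signature pair
#'
#' Runs the full derivation: per pathway, partition the cells by the
#' pathway's per-cell fraction score and compute unique quarter markers;
#' then intersect the c1 and c4 unique-marker lists across all pathways.
#'
#' @param d an [ExpressionDataset-class] (typically neurons only).
#' @param pathways a [GeneSetCollection-class] of co-oriented pathways.
#' @param cfg an [analysisConfig()].
#' @return a [SignaturePair-class] whose provenance records the pathway
#'   names, per-pathway marker counts and per-pathway partitions.
#' @export
deriveSignatures <- function(d, pathways, cfg = analysisConfig()) {
  stopifnot(methods::is(pathways, "GeneSetCollection"))
  d <- if ("logcounts" %in% SummarizedExperiment::assayNames(d)) d else
    normalizeLog1p(d)
  tabs <- lapply(names(pathways), function(nm) {
    sc <- scoreFraction(d, pathways[[nm]])
    quarterUniqueMarkers(d, quartilePartition(sc), cfg)
  })
  names(tabs) <- names(pathways)
  SignaturePair(
    c1Up = intersectQuarterMarkers(tabs, "c1"),
    c4Up = intersectQuarterMarkers(tabs, "c4"),
    provenance = list(
      pathways = names(pathways),
      marker_counts = lapply(tabs, function(t) table(t$quarter))))
}

#' Check that the two signatures oppose each other
#'
#' Computes the per-cell fraction scores of both signatures and their
#' Pearson correlation; the pair passes when the correlation is
#' negative.
#'
#' @param pair a [SignaturePair-class].
#' @param d an [ExpressionDataset-class].
#' @return list(r, p, pass).
#' @export
validateOpposing <- function(pair, d) {
  if (!length(pair@c1Up) || !length(pair@c4Up))
    stop("both signatures must be non-empty")
  s1 <- scoreFraction(d, pair@c1Up)
  s4 <- scoreFraction(d, pair@c4Up)
  ct <- stats::cor.test(s1, s4)
  list(r = unname(ct$estimate), p = ct$p.value,
       pass = unname(ct$estimate) < 0)
}
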