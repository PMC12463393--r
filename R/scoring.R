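#' Per-cell gene-set fraction score
#'
#' The percent of a cell's raw counts falling in the set:
#' `100 * sum(counts[set, cell]) / sum(counts[, cell])`. Computed on raw
#' counts, so the score depends only on within-cell fractions and is
#' invariant to per-cell count scaling. Members absent from the gene
#' universe are ignored; if none are present the score is all-zero with a
#' warning.
#'
#' @param x an [ExpressionDataset-class].
#' @param set character vector of gene symbols (or a single set name with
#'   `collection`).
#' @param ... unused.
#' @return named numeric vector, one percent score in [0, 100] per cell.
#' @name scoreFraction
#' @export
setMethod("scoreFraction", "ExpressionDataset", function(x, set, ...) {
  cts <- SummarizedExperiment::assay(x, "counts")
  total <- Matrix::colSums(cts)
  if (any(total == 0))
    stop("zero-total cell: ", colnames(cts)[which(total == 0)[1L]])
  members <- intersect(as.character(set), rownames(cts))
  if (!length(members)) {
    warning("no set member present in the gene universe; scores are 0")
    return(setNames(numeric(ncol(cts)), colnames(cts)))
  }
  100 * Matrix::colSums(cts[members, , drop = FALSE]) / total
})

#' Score every set of a collection
#'
#' @param x an [ExpressionDataset-class].
#' @param collection a [GeneSetCollection-class].
#' @return cells x sets numeric matrix of percent scores.
#' @export
scoreCollection <- function(x, collection) {
  stopifnot(methods::is(collection, "GeneSetCollection"))
  out <- vapply(names(collection),
                function(nm) suppressWarnings(scoreFraction(x, collection[[nm]])),
                numeric(ncol(x)))
  rownames(out) <- colnames(x)
  out
}

#' Filter transcription factors by mean raw count
#'
#' Keeps the TFs whose mean raw count across all cells is strictly
#' greater than `tf_min_mean` (default 0.1). Symbols absent from the
#' dataset are dropped with a message.
#'
#' @param d an [ExpressionDataset-class].
#' @param tfList character vector of TF symbols; defaults to the genes
#'   flagged `is_tf`.
#' @param cfg an [analysisConfig()].
#' @return character vector of retained TF symbols.
#' @export
filterTFs <- function(d, tfList = NULL, cfg = analysisConfig()) {
  if (is.null(tfList)) tfList <- geneSymbols(d)[isTF(d)]
  missing <- setdiff(tfList, rownames(d))
  if (length(missing))
    message("filterTFs: ", length(missing), " symbol(s) not in dataset")
  tfList <- intersect(tfList, rownames(d))
  if (!length(tfList)) return(character())
  cts <- SummarizedExperiment::assay(d, "counts")
  means <- Matrix::rowSums(cts[tfList, , drop = FALSE]) / ncol(cts)
  kept <- tfList[means > cfg$tf_min_mean]
  if (!length(kept)) message("filterTFs: no TF passed mean > ",
                             cfg$tf_min_mean)
  kept
}

#' TF activity by univariate linear model (ulm)
#'
#' For each cell and TF, ordinary least squares of the cell's normalized
#' expression across all genes on the TF's regulon weight vector (weight
#' 0 for non-targets, intercept included); the activity is the
#' t-statistic of the slope. A cell with constant expression across genes
#' yields activity 0; a regulon whose weight vector has zero variance is
#' reported as `NA`.
#'
#' @param d an [ExpressionDataset-class] (normalized layer computed on
#'   demand).
#' @param regulons data.frame(tf, target, weight); targets absent from
#'   the gene universe are dropped.
#' @return cells x TFs numeric matrix of t-statistics.
#' @export
tfActivityULM <- function(d, regulons) {
  stopifnot(all(c("tf", "target", "weight") %in% colnames(regulons)))
  X <- as.matrix(.logcounts(d))              # genes x cells
  G <- nrow(X)
  regulons <- regulons[regulons$target %in% rownames(X), , drop = FALSE]
  tfs <- unique(regulons$tf)
  W <- matrix(0, G, length(tfs), dimnames = list(rownames(X), tfs))
  W[cbind(match(regulons$target, rownames(X)),
          match(regulons$tf, tfs))] <- regulons$weight
  sw <- apply(W, 2L, sd)
  Wc <- sweep(W, 2L, colMeans(W))
  Xc <- sweep(X, 2L, colMeans(X))
  sy <- sqrt(colSums(Xc^2) / (G - 1))
  num <- crossprod(Xc, Wc) / (G - 1)        # cells x TFs covariances
  r <- sweep(num, 2L, sw, "/") / sy          # 0/0 where sy == 0 -> NaN
  r[sy == 0, ] <- 0                          # constant cell: zero covariance
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((G - 2) / pmax(1 - r^2, .Machine$double.eps))
  tval[, sw == 0] <- NA_real_                # degenerate regulon
  rownames(tval) <- colnames(X)
  tval
}

#' Pairwise Pearson correlation report
#'
#' Pearson r and a two-sided p-value for every column pair between two
#' observation matrices (or all pairs within one). Pairs are flagged
#' significant at raw `corr_p`; the `topK` most positive and most
#' negative pairs by r are listed.
#'
#' @param x cells x features numeric matrix.
#' @param y optional second matrix on the same cells; if `NULL`, all
#'   within-`x` pairs (upper triangle) are reported.
#' @param cfg an [analysisConfig()].
#' @param topK list length for the extremes (default `cfg$screen_k`).
#' @return list with `table` (feature_a, feature_b, r, p, significant),
#'   `top` and `bottom` data.frames.
#' @export
pairwiseCorrelation <- function(x, y = NULL, cfg = analysisConfig(),
                                topK = cfg$screen_k) {
  x <- as.matrix(x)
  self <- is.null(y)
  y <- if (self) x else as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y need the same observations")
  n <- nrow(x)
  if (n < 3) stop("need >= 3 paired observations")
  zx <- apply(x, 2L, sd) == 0
  zy <- apply(y, 2L, sd) == 0
  if (any(zx) || any(zy))
    warning("zero-variance feature(s); correlations reported as NA")
  r <- suppressWarnings(cor(x, y))
  r[zx, ] <- NA_real_
  r[, zy] <- NA_real_
  idx <- which(if (self) upper.tri(r) else matrix(TRUE, ncol(x), ncol(y)),
               arr.ind = TRUE)
  rv <- r[idx]
  tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  tab <- data.frame(feature_a = colnames(x)[idx[, 1L]],
                    feature_b = colnames(y)[idx[, 2L]],
                    r = rv, p = p,
                    significant = !is.na(p) & p < cfg$corr_p,
                    stringsAsFactors = FALSE)
  ord <- order(tab$r, tab$feature_a, tab$feature_b, decreasing = FALSE,
               na.last = NA)
  k <- min(topK, length(ord))
  list(table = tab,
       top = tab[rev(tail(ord, k)), , drop = FALSE],
       bottom = tab[head(ord, k), , drop = FALSE])
}
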