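# Wilcoxon rank-sum statistics of every row of X for each level of a
# factor vs the rest: midrank AUC (= Mann-Whitney win fraction, ties one
# half) and a two-sided normal-approximation p with tie correction.
# Ranks and the tie correction are computed once per row and shared
# across the one-vs-rest comparisons.
.rankSumMulti <- function(X, f) {
  X <- as.matrix(X)
  f <- factor(f)
  n <- ncol(X)
  lv <- levels(f)
  n1 <- tabulate(f, nbins = length(lv))
  stopifnot(all(n1 > 0), length(lv) >= 2)
  auc <- p <- matrix(0, nrow(X), length(lv))
  for (g in seq_len(nrow(X))) {
    x <- X[g, ]
    r <- rank(x)
    cnt <- tabulate(match(x, unique(x)))
    tiecor <- sum(cnt^3 - cnt) / (n * (n - 1))
    rsum <- vapply(seq_along(lv), function(i) sum(r[f == lv[i]]), 0)
    U <- rsum - n1 * (n1 + 1) / 2
    n2 <- n - n1
    auc[g, ] <- U / (n1 * n2)
    v <- n1 * n2 / 12 * ((n + 1) - tiecor)
    z <- ifelse(v > 0, (U - n1 * n2 / 2) / sqrt(v), 0)
    p[g, ] <- ifelse(v > 0, 2 * pnorm(-abs(z)), 1)
  }
  setNames(lapply(seq_along(lv), function(i)
    data.frame(gene = rownames(X), auc = auc[, i], p = pmin(p[, i], 1),
               stringsAsFactors = FALSE)), lv)
}

# two-group convenience wrapper: statistics for mask == TRUE vs rest
.rankSumStats <- function(X, groupMask) {
  .rankSumMulti(X, factor(ifelse(groupMask, "in", "out"),
                          levels = c("in", "out")))[["in"]]
}

# Seurat-style average log fold-change on the log1p-normalized layer:
# ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))
.avgLogFC <- function(lg, maskIn) {
  e <- expm1(lg)
  mi <- Matrix::rowMeans(e[, maskIn, drop = FALSE])
  mo <- Matrix::rowMeans(e[, !maskIn, drop = FALSE])
  log((mi + 1) / (mo + 1))
}

#' auROC ranking of per-cell scores between two groups
#'
#' For each item (pathway, signature or gene) with a per-cell score, the
#' area under the ROC curve separating the two groups: `AUC = U / (n1 *
#' n2)` where `U` is the Mann-Whitney statistic of group-1 vs group-2
#' scores (ties contribute one half), with a two-sided Wilcoxon
#' rank-sum p-value. The comparison is skipped with a message when
#' either group has fewer than `auroc_min_cells` cells (default 15).
#' Items are sorted by descending AUC.
#'
#' @param scores cells x items numeric matrix (rownames = cell ids).
#' @param groups named group label per cell (names = cell ids) or a
#'   vector parallel to rows of `scores`.
#' @param pair character(2) of group labels: AUC is for pair 1 vs 2.
#' @param cfg an [analysisConfig()].
#' @return data.frame(item, auc, p, n1, n2) sorted by descending AUC, or
#'   `NULL` when skipped.
#' @export
aurocRank <- function(scores, groups, pair, cfg = analysisConfig()) {
  scores <- as.matrix(scores)
  if (!is.null(names(groups)) && !is.null(rownames(scores)))
    groups <- groups[rownames(scores)]
  sel <- groups %in% pair
  scores <- scores[sel, , drop = FALSE]
  groups <- groups[sel]
  n1 <- sum(groups == pair[1L]); n2 <- sum(groups == pair[2L])
  if (min(n1, n2) < cfg$auroc_min_cells) {
    message("aurocRank: skipped ", paste(pair, collapse = " vs "), " (",
            n1, "/", n2, " cells; min ", cfg$auroc_min_cells, ")")
    return(NULL)
  }
  st <- .rankSumStats(t(scores), groups == pair[1L])
  out <- data.frame(item = colnames(scores), auc = st$auc, p = st$p,
                    n1 = n1, n2 = n2, stringsAsFactors = FALSE)
  out <- out[order(-out$auc, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression between two groups (bimod likelihood-ratio)
#'
#' Genes passing the expression-fraction (`deg_min_pct`, default 0.1 in
#' at least one group) and fold-change (`|logFC| >= deg_logfc`, default
#' 0.25, Seurat-style on the normalized layer) pre-filters are tested
#' with a 2-df likelihood-ratio test under a zero-inflated model: a
#' point mass at zero plus a normal location model on the positive
#' log-normalized values (detection probability and positive mean differ
#' between groups; the positive-value SD is pooled). P-values are
#' BH-adjusted and the final table keeps genes with
#' `|avg_diff| > deg_avg_diff` (default 0.1, mean difference on the
#' log-normalized scale).
#'
#' @param d an [ExpressionDataset-class].
#' @param pair character(2) group labels (direction is pair 1 minus 2).
#' @param cfg an [analysisConfig()].
#' @return data.frame(gene, avg_logFC, avg_diff, pct_1, pct_2, p, p_adj,
#'   direction).
#' @export
degTest <- function(d, pair, cfg = analysisConfig()) {
  grp <- cellGroups(d)
  m1 <- grp == pair[1L]; m2 <- grp == pair[2L]
  if (sum(m1) < 3 || sum(m2) < 3) stop("both groups need >= 3 cells")
  lg <- .logcounts(d)[, m1 | m2, drop = FALSE]
  in1 <- grp[m1 | m2] == pair[1L]
  pct1 <- Matrix::rowMeans(lg[, in1, drop = FALSE] > 0)
  pct2 <- Matrix::rowMeans(lg[, !in1, drop = FALSE] > 0)
  lfc <- .avgLogFC(lg, in1)
  keep <- pmax(pct1, pct2) >= cfg$deg_min_pct & abs(lfc) >= cfg$deg_logfc &
    (pct1 + pct2) > 0
  if (!any(keep)) return(data.frame())
  lg <- as.matrix(lg[keep, , drop = FALSE])
  p <- apply(lg, 1L, function(x) .bimodLRT(x[in1], x[!in1]))
  avg_diff <- rowMeans(lg[, in1, drop = FALSE]) -
    rowMeans(lg[, !in1, drop = FALSE])
  out <- data.frame(gene = rownames(lg), avg_logFC = lfc[keep],
                    avg_diff = avg_diff,
                    pct_1 = pct1[keep], pct_2 = pct2[keep], p = p,
                    p_adj = p.adjust(p, "BH"),
                    direction = ifelse(avg_diff > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$avg_diff) > cfg$deg_avg_diff, , drop = FALSE]
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 2-df LRT under point-mass-at-zero + normal positive component; the
# positive SD is pooled across both groups so only the detection rate
# and the positive mean differ.
.bimodLRT <- function(x, y) {
  pos <- c(x[x > 0], y[y > 0])
  if (!length(pos)) return(1)
  sigma <- max(sd(pos), 0.1)
  if (is.na(sigma)) sigma <- 0.1
  ll <- function(v) {
    n0 <- sum(v == 0); vp <- v[v > 0]
    pi <- min(max(length(vp) / length(v), 1e-5), 1 - 1e-5)
    n0 * log(1 - pi) + length(vp) * log(pi) +
      sum(stats::dnorm(vp, mean(vp), sigma, log = TRUE))
  }
  lrt <- 2 * (ll(x) + ll(y) - ll(c(x, y)))
  pchisq(max(lrt, 0), df = 2, lower.tail = FALSE)
}
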