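#' Supervised neuron subtyping by defining-gene expression
#'
#' For each catalog row, the subtype's members are exactly the neurons
#' (cells with `cell_type == "Neuron"`) whose raw count for the defining
#' gene is > 0. A cell may belong to many subtypes (overlap is expected
#' and later quantified by the Jaccard similarity). Catalog genes absent
#' from the dataset are skipped with a message.
#'
#' @param d an [ExpressionDataset-class].
#' @param catalog data.frame(subtype, gene, category), see
#'   [readSubtypeCatalog()].
#' @return a [SubtypeAssignment-class].
#' @export
assignSubtypes <- function(d, catalog) {
  catalog <- validateSubtypeCatalog(catalog)
  neurons <- cellTypes(d) == "Neuron"
  if (!any(neurons)) stop("no neurons in dataset")
  cts <- SummarizedExperiment::assay(d, "counts")
  ids <- colnames(cts)[neurons]
  missing <- !catalog$gene %in% rownames(cts)
  if (any(missing)) {
    message("assignSubtypes: skipping ", sum(missing),
            " catalog gene(s) absent from dataset: ",
            paste(head(catalog$gene[missing], 5), collapse = ", "))
    catalog <- catalog[!missing, , drop = FALSE]
  }
  expr <- cts[catalog$gene, neurons, drop = FALSE] > 0
  members <- lapply(seq_len(nrow(catalog)), function(k) ids[expr[k, ]])
  names(members) <- catalog$subtype
  methods::new("SubtypeAssignment",
               members = members,
               category = setNames(catalog$category, catalog$subtype),
               definingGene = setNames(catalog$gene, catalog$subtype),
               neuronIds = ids,
               neuronGroups = setNames(cellGroups(d)[neurons], ids))
}

#' Rank subtypes by member cell count within a group
#'
#' Subtypes with fewer than `subtype_min_cells` members (default 10) in
#' the reference group are excluded; the remainder are sorted by
#' descending member count within each category, ties broken
#' alphabetically.
#'
#' @param a a [SubtypeAssignment-class].
#' @param group reference group label.
#' @param cfg an [analysisConfig()].
#' @return data.frame(subtype, category, n, rank) with rank within
#'   category.
#' @export
countRank <- function(a, group, cfg = analysisConfig()) {
  in_group <- names(a@neuronGroups)[a@neuronGroups == group]
  n <- vapply(a@members, function(m) sum(m %in% in_group), 0L)
  df <- data.frame(subtype = names(n), category = a@category[names(n)],
                   n = as.integer(n), stringsAsFactors = FALSE)
  df <- df[df$n >= cfg$subtype_min_cells, , drop = FALSE]
  df <- df[order(df$category, -df$n, df$subtype), , drop = FALSE]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$category)[unique(df$category)],
                           seq_along), use.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Weighted subtype proportions per group
#'
#' The proportion of a subtype in a group is its member count in that
#' group divided by the group's total neuron count (the weighting against
#' per-group neuron totals). The cross-group relative share rescales each
#' subtype's per-group proportions to sum to one, the display used for
#' comparing groups within a subtype.
#'
#' @param a a [SubtypeAssignment-class].
#' @return list with `counts`, `proportion` and `relative` matrices
#'   (subtypes x groups) and `neurons_per_group`.
#' @export
weightedProportions <- function(a) {
  groups <- intersect(VALID_GROUPS, unique(a@neuronGroups))
  totals <- vapply(groups, function(g) sum(a@neuronGroups == g), 0L)
  if (any(totals == 0)) stop("group with zero neurons: ",
                             groups[which(totals == 0)[1L]])
  cnt <- vapply(groups, function(g) {
    ids <- names(a@neuronGroups)[a@neuronGroups == g]
    vapply(a@members, function(m) sum(m %in% ids), 0L)
  }, integer(length(a@members)))
  cnt <- matrix(cnt, nrow = length(a@members),
                dimnames = list(names(a@members), groups))
  prop <- sweep(cnt, 2L, totals, "/")
  rs <- rowSums(prop)
  rel <- prop / ifelse(rs > 0, rs, 1)
  list(counts = cnt, proportion = prop, relative = rel,
       neurons_per_group = totals)
}

#' Subtype-subtype similarity
#'
#' Two complementary similarity readings per subtype pair: the Pearson
#' correlation of their mean normalized expression profiles, and the
#' Jaccard index of their member sets (which quantifies how much apparent
#' profile similarity reflects shared cells).
#'
#' @param a a [SubtypeAssignment-class].
#' @param d the [ExpressionDataset-class] the assignment came from.
#' @param cfg an [analysisConfig()]; subtypes below `subtype_min_cells`
#'   total members are excluded.
#' @param genes optional gene panel (default: all genes).
#' @return list with `profile` (Pearson r) and `jaccard` matrices.
#' @export
subtypeSimilarity <- function(a, d, cfg = analysisConfig(), genes = NULL) {
  keep <- names(a@members)[lengths(a@members) >= cfg$subtype_min_cells]
  if (length(keep) < 2) stop("need >= 2 subtypes with >= ",
                             cfg$subtype_min_cells, " members")
  lg <- .logcounts(d)
  if (!is.null(genes)) lg <- lg[intersect(genes, rownames(lg)), ,
                                drop = FALSE]
  prof <- vapply(keep, function(s)
    Matrix::rowMeans(lg[, a@members[[s]], drop = FALSE]),
    numeric(nrow(lg)))
  zv <- apply(prof, 2L, sd) == 0
  r <- suppressWarnings(cor(prof))
  r[zv, ] <- NA_real_; r[, zv] <- NA_real_
  diag(r) <- 1
  jac <- outer(keep, keep, Vectorize(function(i, j) {
    mi <- a@members[[i]]; mj <- a@members[[j]]
    length(intersect(mi, mj)) / length(union(mi, mj))
  }))
  dimnames(jac) <- dimnames(r) <- list(keep, keep)
  list(profile = r, jaccard = jac)
}
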