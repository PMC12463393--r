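#' Rank subtypes by mean score within a reference group
#'
#' For each score set (a per-cell score vector: pathway, signature or
#' gene set), each subtype is summarized by the mean and standard
#' deviation of the score over the subtype's cells belonging to the
#' reference group, then ranked by descending mean (ties alphabetical).
#' Subtypes with fewer than `subtype_min_cells` cells in the reference
#' group are excluded. Top-K and bottom-K lists (K = `screen_k`, default
#' 20) are recorded per score set; when K exceeds the number of ranked
#' subtypes the whole list is used and a message is logged.
#'
#' @param a a [SubtypeAssignment-class].
#' @param scoreTables named list of per-cell score vectors (names = cell
#'   ids), or a cells x sets matrix.
#' @param refGroup reference group label.
#' @param cfg an [analysisConfig()].
#' @return list with `stats` (long data.frame: set, subtype, mean, sd,
#'   n, rank), `top` and `bottom` (named lists of subtype vectors).
#' @export
rankSubtypeScores <- function(a, scoreTables, refGroup,
                              cfg = analysisConfig()) {
  if (is.matrix(scoreTables))
    scoreTables <- setNames(lapply(seq_len(ncol(scoreTables)), function(j)
      setNames(scoreTables[, j], rownames(scoreTables))),
      colnames(scoreTables))
  ref_ids <- names(a@neuronGroups)[a@neuronGroups == refGroup]
  stats <- lapply(names(scoreTables), function(nm) {
    sc <- scoreTables[[nm]]
    rows <- lapply(names(a@members), function(s) {
      cells <- intersect(a@members[[s]], ref_ids)
      if (length(cells) < cfg$subtype_min_cells) return(NULL)
      v <- sc[cells]
      data.frame(set = nm, subtype = s, mean = mean(v),
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) return(NULL)
    df <- df[order(-df$mean, df$subtype), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  })
  stats <- do.call(rbind, stats)
  if (is.null(stats)) stop("no subtype passed subtype_min_cells in ",
                           refGroup)
  k <- cfg$screen_k
  split_sets <- split(stats, stats$set)[unique(stats$set)]
  top <- lapply(split_sets, function(df) {
    if (k > nrow(df)) message("rankSubtypeScores: K=", k, " > ",
                              nrow(df), " subtypes; using all")
    df$subtype[seq_len(min(k, nrow(df)))]
  })
  bottom <- lapply(split_sets, function(df) {
    kk <- min(k, nrow(df))
    df$subtype[seq(nrow(df) - kk + 1L, nrow(df))]
  })
  rownames(stats) <- NULL
  list(stats = stats, top = top, bottom = bottom)
}

#' Intersection screen over top / bottom rank lists
#'
#' Returns the subtypes appearing in at least `screen_min_hits` (default
#' 4) of the score sets' top-K lists, and separately of the bottom-K
#' lists, with their hit counts. Enlarging K never removes a hit.
#'
#' @param ranks result of [rankSubtypeScores()].
#' @param cfg an [analysisConfig()].
#' @return list(top =, bottom =) of data.frame(subtype, hits).
#' @export
intersectionScreen <- function(ranks, cfg = analysisConfig()) {
  if (length(ranks$top) < cfg$screen_min_hits)
    stop("need at least screen_min_hits (", cfg$screen_min_hits,
         ") score sets")
  tally <- function(lists) {
    tab <- sort(table(unlist(lists)), decreasing = TRUE)
    hits <- tab[tab >= cfg$screen_min_hits]
    df <- data.frame(subtype = names(hits), hits = as.integer(hits),
                     stringsAsFactors = FALSE)
    df[order(-df$hits, df$subtype), , drop = FALSE]
  }
  list(top = tally(ranks$top), bottom = tally(ranks$bottom))
}

#' Over-representation analysis (hypergeometric)
#'
#' For each gene set, the one-sided hypergeometric tail probability of
#' an overlap at least as large as observed between the query gene list
#' and the set, both restricted to the universe; BH FDR across sets,
#' significant at FDR < `ora_fdr` (default 0.05). An empty query yields
#' p = 1 everywhere.
#'
#' @param genes character vector of query genes (e.g. DEGs).
#' @param sets a [GeneSetCollection-class].
#' @param universe character vector of background genes; `genes` must be
#'   a subset.
#' @param cfg an [analysisConfig()].
#' @return data.frame(set, overlap, set_size, p, fdr, significant).
#' @export
oraEnrich <- function(genes, sets, universe, cfg = analysisConfig()) {
  stopifnot(methods::is(sets, "GeneSetCollection"))
  genes <- unique(genes)
  if (length(setdiff(genes, universe)))
    stop("query genes must be a subset of the universe")
  N <- length(unique(universe))
  k <- length(genes)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(genes, s))
    p <- if (k == 0) 1 else
      stats::phyper(ov - 1, length(s), N - length(s), k,
                    lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(s), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- out$fdr < cfg$ora_fdr
  out[order(out$p, out$set), , drop = FALSE]
}
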