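#' Subtype perturbation prioritization by subsampled classifier AUC
#'
#' Ranks neuron subtypes by how separable two conditions are from
#' expression. Per subtype, `augur_n_subsamples` times (default 50):
#' draw `augur_subsample_size` cells per condition (default 6) without
#' replacement, train a random-forest (decision-tree ensemble)
#' classifier on the subtype's most variable genes under stratified
#' 3-fold cross-validation, and record the AUC of the out-of-fold
#' condition predictions. The reported score is the mean AUC over
#' subsamples; subtypes are sorted descending. Subtypes with fewer than
#' `augur_min_cells` cells (default 6) in either condition are skipped
#' with a message.
#'
#' @param d an [ExpressionDataset-class].
#' @param a a [SubtypeAssignment-class].
#' @param pair character(2), the two group labels to compare.
#' @param cfg an [analysisConfig()]; `seed` drives all subsampling.
#' @return data.frame(subtype, mean_auc, n_subsamples, n_cells_1,
#'   n_cells_2, pair), sorted by descending mean AUC (ties alphabetical).
#' @export
prioritizeSubtypes <- function(d, a, pair, cfg = analysisConfig()) {
  stopifnot(length(pair) == 2)
  lg <- .logcounts(d)
  grp <- a@neuronGroups
  res <- .withSeed(cfg$seed, {
    lapply(sort(names(a@members)), function(s) {
      m1 <- intersect(a@members[[s]], names(grp)[grp == pair[1L]])
      m2 <- intersect(a@members[[s]], names(grp)[grp == pair[2L]])
      if (length(m1) < cfg$augur_min_cells ||
          length(m2) < cfg$augur_min_cells) {
        message("prioritizeSubtypes: skipping ", s, " (", length(m1), "/",
                length(m2), " cells; min ", cfg$augur_min_cells, ")")
        return(NULL)
      }
      X <- Matrix::t(lg[, c(m1, m2), drop = FALSE])
      v <- apply(X, 2L, var)
      nf <- min(cfg$augur_n_features, sum(v > 0))
      X <- as.matrix(X[, order(-v)[seq_len(nf)], drop = FALSE])
      y <- rep(pair, c(length(m1), length(m2)))
      aucs <- vapply(seq_len(cfg$augur_n_subsamples), function(r) {
        i1 <- sample(seq_along(m1), cfg$augur_subsample_size)
        i2 <- length(m1) + sample(seq_along(m2), cfg$augur_subsample_size)
        .cvAuc(X[c(i1, i2), , drop = FALSE], y[c(i1, i2)], cfg)
      }, 0)
      data.frame(subtype = s, mean_auc = mean(aucs),
                 n_subsamples = cfg$augur_n_subsamples,
                 n_cells_1 = length(m1), n_cells_2 = length(m2),
                 pair = paste(pair, collapse = " vs "),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no subtype had >= ", cfg$augur_min_cells,
                         " cells in both groups")
  out <- out[order(-out$mean_auc, out$subtype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# stratified k-fold CV random forest; AUC of out-of-fold probabilities
.cvAuc <- function(X, y, cfg) {
  y <- factor(y)
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(cfg$augur_cv_folds), length(idx))
  }
  prob <- numeric(length(y))
  for (f in seq_len(cfg$augur_cv_folds)) {
    tr <- folds != f
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                          num.trees = cfg$augur_n_trees,
                          probability = TRUE,
                          min.node.size = cfg$augur_min_node,
                          num.threads = 1L,
                          seed = sample.int(.Machine$integer.max, 1L))
    prob[!tr] <- predict(fit, X[!tr, , drop = FALSE],
                         num.threads = 1L)$predictions[, levels(y)[2L]]
  }
  .aucFromScores(prob[y == levels(y)[2L]], prob[y == levels(y)[1L]])
}

# Mann-Whitney AUC of scores1 vs scores2 (ties count one half)
.aucFromScores <- function(scores1, scores2) {
  n1 <- length(scores1); n2 <- length(scores2)
  r <- rank(c(scores1, scores2))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
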