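# Shared builders for small in-code fixtures.

# minimal dataset from an explicit genes x cells matrix
tinyDataset <- function(counts, groups = NULL, cell_types = "Neuron",
                        mito = NULL, tf = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", 1:ng)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%02d", 1:nc)
  if (is.null(groups)) groups <- rep_len(c("Y", "O", "O.T"), nc)
  if (is.null(mito)) mito <- rep(FALSE, ng)
  if (is.null(tf)) tf <- rep(FALSE, ng)
  ExpressionDataset(
    counts,
    cellData = data.frame(cell_id = colnames(counts), group = groups,
                          cell_type = rep_len(cell_types, nc)),
    geneData = data.frame(symbol = rownames(counts), is_mito = mito,
                          is_tf = tf))
}

# brute-force all-pairs AUC oracle (ties count one half)
bruteAuc <- function(x1, x2) {
  wins <- 0
  for (a in x1) for (b in x2) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(x1) * length(x2))
}

# the perturbation-recovery study design: flat programs, ten peptide
# subtypes, one subtype's program genes shifted in O.T
perturbScenario <- function(seed) {
  genes <- defaultSubtypeGenes()
  genes <- genes[genes$category == "peptide", ][1:10, ]
  genes[c("p_Y", "p_O", "p_OT")] <- 0.3
  simExpressionConfig(
    n_cells_per_group = c(Y = 300, O = 300, "O.T" = 300),
    n_genes = 800, neuron_fraction = 0.9, qc_violator_fraction = 0,
    subtype_genes = genes,
    program_A_intensity = c(Y = 1, O = 1, "O.T" = 1),
    program_B_intensity = c(Y = 1, O = 1, "O.T" = 1),
    perturb = list(subtype = "Sct", multiplier = c(Y = 1, O = 1, "O.T" = 3)),
    seed = seed)
}

# the signature-recovery study design: 3000 neurons, aging-like
# opposing-program intensities
signatureScenario <- function(seed) {
  simExpressionConfig(
    n_cells_per_group = c(Y = 1250, O = 1250, "O.T" = 1250),
    neuron_fraction = 0.8, qc_violator_fraction = 0, seed = seed)
}
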