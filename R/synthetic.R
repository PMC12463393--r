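#' Configuration for the synthetic expression generator
#'
#' Describes a three-group (Y = young, O = old, O.T = old + treatment)
#' single-nucleus dataset with planted, recoverable structure: an
#' overdispersed negative-binomial count law with log-normal baseline
#' means; two disjoint transcriptional programs ("A", metabolic-like, and
#' "B", synaptic-like) whose per-group intensity differs and which are
#' anti-correlated within cells through a shared latent activity axis;
#' sparse near-binary neuropeptide/receptor genes defining overlapping
#' neuron subtypes; flagged mitochondrial genes; and explicitly planted
#' QC-violating cells.
#'
#' @param n_cells_per_group named integer vector over exactly
#'   `c("Y","O","O.T")`.
#' @param n_genes total gene-universe size (must fit all named genes).
#' @param n_celltypes number of coarse cell types (neurons dominant).
#' @param neuron_fraction fraction of cells that are neurons, in (0, 1].
#' @param subtype_genes data.frame(gene, category, p_Y, p_O, p_OT):
#'   per-group probability that a neuron expresses the gene (count >= 1);
#'   ~0 outside neurons.
#' @param program_A_genes,program_B_genes disjoint symbol vectors.
#' @param program_A_intensity,program_B_intensity named multipliers per
#'   group applied to the program genes' means.
#' @param program_base_mean baseline mean count of program genes.
#' @param program_anticorr_sd scale of the shared latent axis that makes
#'   the two programs anti-correlated across cells (0 disables).
#' @param mito_gene_count number of mitochondrial genes (`mt-1`, ...).
#' @param qc_violator_fraction fraction of cells planted to violate QC
#'   (alternately high-UMI and high-mito).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2), shared across genes.
#' @param baseline_meanlog,baseline_sdlog log-normal law of baseline
#'   filler-gene means.
#' @param perturb optional planted perturbation:
#'   `list(subtype =, genes =, multiplier = named per-group vector)`;
#'   the means of `genes` are multiplied by `multiplier[group]` in cells
#'   belonging to that subtype.
#' @param seed integer RNG seed.
#' @return validated list of class `simExpressionConfig`.
#' @export
simExpressionConfig <- function(n_cells_per_group = c(Y = 500, O = 500, "O.T" = 500),
                                n_genes = 1500,
                                n_celltypes = 10,
                                neuron_fraction = 0.6,
                                subtype_genes = defaultSubtypeGenes(),
                                program_A_genes = sprintf("MetG%02d", 1:25),
                                program_B_genes = sprintf("SynG%02d", 1:25),
                                program_A_intensity = c(Y = 1, O = 3, "O.T" = 2),
                                program_B_intensity = c(Y = 3, O = 1, "O.T" = 2),
                                program_base_mean = 2,
                                program_anticorr_sd = 0.5,
                                mito_gene_count = 10,
                                qc_violator_fraction = 0.02,
                                nb_dispersion = 0.4,
                                baseline_meanlog = log(0.3),
                                baseline_sdlog = 1,
                                perturb = NULL,
                                seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("n_cells_per_group", "program_A_intensity",
              "program_B_intensity")) {
    cfg[[f]] <- unlist(cfg[[f]])
    # a bare Y key in a YAML 1.1 config arrives as boolean TRUE
    names(cfg[[f]])[names(cfg[[f]]) == "TRUE"] <- "Y"
  }
  if (!setequal(names(cfg$n_cells_per_group), VALID_GROUPS))
    stop("n_cells_per_group must be named exactly {",
         paste(VALID_GROUPS, collapse = ", "), "}")
  if (any(cfg$n_cells_per_group < 1)) stop("cell counts must be positive")
  if (length(intersect(cfg$program_A_genes, cfg$program_B_genes)))
    stop("program gene lists must be disjoint")
  for (f in c("neuron_fraction", "qc_violator_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$neuron_fraction == 0) stop("neuron_fraction must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  pcols <- c("p_Y", "p_O", "p_OT")
  stopifnot(all(c("gene", "category", pcols) %in% colnames(cfg$subtype_genes)))
  if (any(as.matrix(cfg$subtype_genes[, pcols]) < 0 |
          as.matrix(cfg$subtype_genes[, pcols]) > 1))
    stop("subtype expression probabilities must lie in [0, 1]")
  named <- length(cfg$program_A_genes) + length(cfg$program_B_genes) +
    nrow(cfg$subtype_genes) + cfg$mito_gene_count
  if (cfg$n_genes < named)
    stop("n_genes (", cfg$n_genes, ") smaller than required named genes (",
         named, ")")
  class(cfg) <- c("simExpressionConfig", "list")
  cfg
}

#' Default planted subtype-defining genes
#'
#' A small catalog in the spirit of hypothalamic neuropeptide /
#' receptor subtyping: peptide genes (Oxt, Avp, Crh, ...) and receptor
#' genes (Esr1, Insr, ...) with per-group neuron expression
#' probabilities.
#'
#' @return data.frame(gene, category, p_Y, p_O, p_OT).
#' @export
defaultSubtypeGenes <- function() {
  pep <- c("Oxt", "Avp", "Crh", "Agrp", "Pomc", "Gnrh1", "Kiss1", "Sct",
           "Ghrl", "Npy", "Vip", "Gal")
  rec <- c("Esr1", "Insr", "Prlr", "Mc3r", "Lepr", "Oxtr", "Ghsr", "Npy1r")
  p <- c(0.35, 0.3, 0.3, 0.25, 0.25, 0.2, 0.2, 0.2, 0.15, 0.3, 0.1, 0.25,
         0.3, 0.25, 0.25, 0.2, 0.2, 0.15, 0.1, 0.2)
  data.frame(gene = c(pep, rec),
             category = rep(c("peptide", "receptor"), c(length(pep), length(rec))),
             p_Y = p, p_O = p, p_OT = p, stringsAsFactors = FALSE)
}

#' Simulate a three-group expression dataset with planted truth
#'
#' Draws counts from the negative-binomial model described in
#' [simExpressionConfig()]. Program genes' means are multiplied by the
#' group intensity and by `exp(+/- program_anticorr_sd * u)` for a
#' per-cell latent `u ~ N(0,1)` (plus for program A, minus for program
#' B), making the two programs anti-correlated. Subtype genes are
#' near-binary in neurons (count >= 1 with the configured per-group
#' probability) and zero elsewhere. QC violators are planted explicitly:
#' alternate cells receive an inflated filler-gene count (total UMI >=
#' 8000) or an inflated mitochondrial count (mito percent >= 15). A
#' fixed seed gives bit-identical output.
#'
#' @param config a [simExpressionConfig()].
#' @return `list(dataset =` [ExpressionDataset-class]`, truth = list)`;
#'   truth records program memberships and intensities, the latent axis,
#'   subtype membership, perturbed subtype names and QC-violator ids.
#' @export
simulateExpression <- function(config = simExpressionConfig()) {
  stopifnot(inherits(config, "simExpressionConfig"))
  .withSeed(config$seed, {
    groups <- rep(names(config$n_cells_per_group), config$n_cells_per_group)
    nc <- length(groups)
    cell_id <- sprintf("%s_%04d", gsub("\\.", "", groups),
                       unlist(lapply(config$n_cells_per_group, seq_len)))
    other_types <- c("Astro", "Oligo", "Micro", "OPC", "Endo", "Epend",
                     "Tany", "VLMC", "Peri")[seq_len(max(config$n_celltypes - 1, 1))]
    cell_type <- unlist(lapply(config$n_cells_per_group, function(n) {
      n_neu <- round(config$neuron_fraction * n)
      c(rep("Neuron", n_neu),
        rep_len(other_types, n - n_neu))
    }))
    mito_genes <- if (config$mito_gene_count > 0)
      sprintf("mt-%d", seq_len(config$mito_gene_count)) else character()
    named <- c(config$program_A_genes, config$program_B_genes,
               config$subtype_genes$gene, mito_genes)
    if (anyDuplicated(named)) stop("named gene lists overlap")
    n_fill <- config$n_genes - length(named)
    fillers <- sprintf("Gene%04d", seq_len(n_fill))
    genes <- c(config$program_A_genes, config$program_B_genes, mito_genes,
               fillers, config$subtype_genes$gene)
    base_mean <- c(rep(config$program_base_mean,
                       length(config$program_A_genes) +
                         length(config$program_B_genes)),
                   rep(1, length(mito_genes)),
                   exp(rnorm(n_fill, config$baseline_meanlog,
                             config$baseline_sdlog)),
                   rep(0, nrow(config$subtype_genes)))
    names(base_mean) <- genes
    n_nb <- length(genes) - nrow(config$subtype_genes)  # NB-modelled genes
    mu <- matrix(base_mean[seq_len(n_nb)], n_nb, nc)
    u <- rnorm(nc)
    iA <- match(config$program_A_genes, genes)
    iB <- match(config$program_B_genes, genes)
    fA <- config$program_A_intensity[groups] *
      exp(config$program_anticorr_sd * u)
    fB <- config$program_B_intensity[groups] *
      exp(-config$program_anticorr_sd * u)
    mu[iA, ] <- sweep(mu[iA, , drop = FALSE], 2L, fA, "*")
    mu[iB, ] <- sweep(mu[iB, , drop = FALSE], 2L, fB, "*")
    # near-binary subtype genes, neurons only
    neurons <- cell_type == "Neuron"
    pcol <- c(Y = "p_Y", O = "p_O", "O.T" = "p_OT")
    sub_on <- matrix(FALSE, nrow(config$subtype_genes), nc,
                     dimnames = list(config$subtype_genes$gene, cell_id))
    for (k in seq_len(nrow(config$subtype_genes))) {
      p <- unlist(config$subtype_genes[k, pcol[groups]])
      sub_on[k, ] <- neurons & (runif(nc) < p)
    }
    # planted perturbation acts on the member cells of one subtype
    if (!is.null(config$perturb)) {
      pb <- config$perturb
      if (is.null(pb$genes))
        pb$genes <- c(config$program_A_genes, config$program_B_genes)
      if (!pb$subtype %in% rownames(sub_on))
        stop("perturbed subtype not in catalog: ", pb$subtype)
      target <- sub_on[pb$subtype, ]
      ig <- match(pb$genes, genes)
      if (anyNA(ig)) stop("perturb genes absent from universe")
      fac <- ifelse(target, pb$multiplier[groups], 1)
      mu[ig, ] <- sweep(mu[ig, , drop = FALSE], 2L, fac, "*")
    }
    counts <- matrix(rnbinom(n_nb * nc, size = 1 / config$nb_dispersion,
                             mu = mu),
                     n_nb, nc)
    sub_counts <- matrix(0, nrow(config$subtype_genes), nc)
    non0 <- which(sub_on)
    sub_counts[non0] <- 1 + rpois(length(non0), 0.7)
    counts <- rbind(counts, sub_counts)
    dimnames(counts) <- list(genes, cell_id)
    # planted QC violators: alternate UMI / mito
    n_viol <- round(config$qc_violator_fraction * nc)
    viol <- if (n_viol > 0) sort(sample.int(nc, n_viol)) else integer()
    umi_viol <- viol[seq_along(viol) %% 2 == 1]
    mito_viol <- setdiff(viol, umi_viol)
    if (length(umi_viol))
      counts[match(fillers[1L], genes), umi_viol] <- 9000
    if (length(mito_viol) && length(mito_genes))
      counts[match(mito_genes[1L], genes), mito_viol] <-
        pmax(Matrix::colSums(counts[, mito_viol, drop = FALSE]), 50)
    geneData <- data.frame(symbol = genes,
                           is_mito = genes %in% mito_genes,
                           is_tf = FALSE, stringsAsFactors = FALSE)
    cellData <- data.frame(cell_id = cell_id, group = groups,
                           cell_type = cell_type, stringsAsFactors = FALSE)
    d <- ExpressionDataset(counts, cellData, geneData)
    truth <- list(
      program_A = config$program_A_genes,
      program_B = config$program_B_genes,
      program_A_intensity = config$program_A_intensity,
      program_B_intensity = config$program_B_intensity,
      latent = setNames(u, cell_id),
      subtype_members = apply(sub_on, 1L, function(z) cell_id[z],
                              simplify = FALSE),
      perturbed_subtypes = if (is.null(config$perturb)) character()
      else config$perturb$subtype,
      qc_violators = cell_id[viol],
      qc_umi_violators = cell_id[umi_viol],
      qc_mito_violators = cell_id[mito_viol],
      fillers = fillers)
    list(dataset = d, truth = truth)
  })
}

#' Synthetic pathways tracking the planted metabolic program
#'
#' Builds `nPathways` gene sets that all track planted program A (each a
#' random subset of program-A genes plus filler noise genes), emulating a
#' family of co-oriented metabolic pathways whose quartile partitions can
#' be intersected for signature derivation.
#'
#' @param truth the truth record from [simulateExpression()].
#' @param nPathways number of sets (default 6).
#' @param nProgram program-A genes per set.
#' @param nFiller filler genes per set.
#' @param seed RNG seed.
#' @return a [GeneSetCollection-class].
#' @export
makeSyntheticPathways <- function(truth, nPathways = 6, nProgram = 15,
                                  nFiller = 10, seed = 1L) {
  .withSeed(seed, {
    sets <- lapply(seq_len(nPathways), function(i) {
      c(sample(truth$program_A, min(nProgram, length(truth$program_A))),
        sample(truth$fillers, min(nFiller, length(truth$fillers))))
    })
    names(sets) <- sprintf("synthetic_pathway_%d", seq_len(nPathways))
    GeneSetCollection(sets, source = "synthetic")
  })
}

#' Subtype catalog implied by a simulation config
#'
#' @param config a [simExpressionConfig()].
#' @return data.frame(subtype, gene, category) with subtype named after
#'   its defining gene.
#' @export
simSubtypeCatalog <- function(config) {
  data.frame(subtype = config$subtype_genes$gene,
             gene = config$subtype_genes$gene,
             category = config$subtype_genes$category,
             stringsAsFactors = FALSE)
}

#' Configuration for the paired GWAS simulator
#'
#' @param n_snps number of independent SNPs (LD r2 = 0 by construction).
#' @param exposure_effect_sd SD of true per-allele exposure effects.
#' @param causal_effect true causal effect of exposure on outcome.
#' @param pleiotropy_sd SD of direct (horizontal-pleiotropy) SNP effects
#'   on the outcome; `pleiotropy_mean` shifts them directionally.
#' @param pleiotropy_mean mean of the pleiotropic effects.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 2).
#' @param maf_range c(lo, hi) within (0, 0.5].
#' @param weak_fraction fraction of SNPs simulated with tiny exposure
#'   effects (weak instruments).
#' @param seed RNG seed.
#' @return validated list of class `gwasSimConfig`.
#' @export
gwasSimConfig <- function(n_snps = 150, exposure_effect_sd = 0.035,
                          causal_effect = 0, pleiotropy_sd = 0,
                          pleiotropy_mean = 0,
                          n_exposure = 50000, n_outcome = 20000,
                          maf_range = c(0.1, 0.4), weak_fraction = 0,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$maf_range <- unlist(cfg$maf_range)
  if (cfg$n_exposure < 2 || cfg$n_outcome < 2)
    stop("GWAS sample sizes must be >= 2")
  if (cfg$maf_range[1L] <= 0 || cfg$maf_range[2L] > 0.5)
    stop("maf_range must lie in (0, 0.5]")
  if (cfg$weak_fraction < 0 || cfg$weak_fraction > 1)
    stop("weak_fraction must lie in [0, 1]")
  if (cfg$n_snps < 1) stop("n_snps must be positive")
  class(cfg) <- c("gwasSimConfig", "list")
  cfg
}

#' Simulate a paired exposure / outcome GWAS summary dataset
#'
#' Per SNP, the true exposure effect is `b ~ N(0, exposure_effect_sd^2)`
#' (scaled down 20x for the `weak_fraction` of weak instruments); the
#' true outcome effect is `causal_effect * b + alpha` with pleiotropy
#' `alpha ~ N(pleiotropy_mean, pleiotropy_sd^2)`. Estimated betas add
#' sampling noise with the standard standard error
#' `1 / sqrt(2 * maf * (1 - maf) * n)`; p-values come from the Wald
#' statistic. Allele pairs are non-palindromic so harmonization is
#' lossless. SNPs are mutually independent.
#'
#' @param config a [gwasSimConfig()].
#' @return `list(exposure =, outcome =` GWAS data.frames per [readGwas()]
#'   `, truth = list)`.
#' @export
simulateGwasPair <- function(config = gwasSimConfig()) {
  stopifnot(inherits(config, "gwasSimConfig"))
  .withSeed(config$seed, {
    k <- config$n_snps
    maf <- runif(k, config$maf_range[1L], config$maf_range[2L])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    weak <- runif(k) < config$weak_fraction
    b <- rnorm(k, 0, config$exposure_effect_sd * ifelse(weak, 0.05, 1))
    alpha <- rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd)
    bx <- b + rnorm(k, 0, se_x)
    by <- config$causal_effect * b + alpha + rnorm(k, 0, se_y)
    pairs <- cbind(c("A", "A", "T", "T", "G", "C", "G", "C"),
                   c("G", "C", "G", "C", "A", "A", "T", "T"))
    pick <- sample.int(nrow(pairs), k, replace = TRUE)
    mk <- function(beta, se, n) data.frame(
      snp = sprintf("rs%06d", seq_len(k)),
      effect_allele = pairs[pick, 1L], other_allele = pairs[pick, 2L],
      beta = beta, se = se,
      pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
      eaf = maf, n = n, stringsAsFactors = FALSE)
    list(exposure = mk(bx, se_x, config$n_exposure),
         outcome = mk(by, se_y, config$n_outcome),
         truth = list(causal_effect = config$causal_effect,
                      true_exposure_beta = b, pleiotropy = alpha,
                      weak = weak))
  })
}

#' Deterministic 60-cell toy fixture
#'
#' A hand-specified 60-cell x 100-gene dataset built from a fixed
#' arithmetic pattern (no RNG): 20 cells per group, 40 neurons, 5
#' mitochondrial genes, and exactly 3 cells violating the UMI bound
#' (total >= 8000) plus 2 violating the mitochondrial bound (percent >=
#' 15), so QC retains exactly 55 of 60 cells. Regenerating and writing it
#' yields byte-identical files.
#'
#' @return an [ExpressionDataset-class].
#' @export
makeToyFixture <- function() {
  n_genes <- 100L; n_cells <- 60L
  symbols <- c("Oxt", "Avp", "Crh", sprintf("G%03d", 4:95),
               sprintf("mt-%d", 1:5))
  counts <- outer(seq_len(95L), seq_len(n_cells),
                  function(i, j) (i + 2L * j) %% 3L)
  mito <- outer(96:100, seq_len(n_cells), function(i, j) (i + j) %% 2L)
  counts <- rbind(counts, mito)
  counts[4L, 1:3] <- c(9000L, 9500L, 10000L)   # UMI violators
  counts[96L, 4:5] <- 60L                      # mito violators
  geneData <- data.frame(symbol = symbols,
                         is_mito = c(rep(FALSE, 95L), rep(TRUE, 5L)),
                         is_tf = symbols %in% c("G010", "G011"),
                         stringsAsFactors = FALSE)
  cellData <- data.frame(
    cell_id = sprintf("C%02d", seq_len(n_cells)),
    group = rep(c("Y", "O", "O.T"), each = 20L),
    cell_type = ifelse(seq_len(n_cells) %% 3L == 0L, "Astro", "Neuron"),
    stringsAsFactors = FALSE)
  ExpressionDataset(counts, cellData, geneData)
}
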