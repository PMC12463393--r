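---
title: "Methods: supervised subtyping, opposing signatures and MR screening"
author: "hypoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised subtyping, opposing signatures and MR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hypoScreen` packages the analytical core of a three-group hypothalamus
single-nucleus RNA-seq study design — young (Y), old (O) and old-treated
(O.T) animals — together with a bidirectional two-sample Mendelian
randomization (MR) screen for endocrine factors. The expression side runs
from raw cell × gene counts to prioritized neuron subtypes; the genetics
side runs from GWAS summary statistics to a classified causal direction.
Everything is exercisable on synthetic data with planted, recoverable
ground truth, so every stage is testable offline.

# The expression model and its stages

## Quality control

Cells with an unusually high total UMI count (≥ 8000) or a high
mitochondrial percentage (≥ 15%) are removed. Both bounds are *inclusive
on the removal side* — a cell at exactly the bound is dropped — and both
are configurable (`qc_max_umi`, `qc_max_mito_pct`). Mitochondrial genes
are identified by an explicit `is_mito` flag in the gene table rather
than by symbol prefix, because rat symbol conventions vary between
annotation builds.

## Normalization

Marker detection and profile comparison need a variance-stabilized
layer; fraction scoring and the subtype membership rule deliberately do
not. We therefore keep raw counts as the primary assay and add a
counts-per-10,000, `log(1 + x)` layer (`normalizeLog1p()`), the default
of the standard single-cell toolchains. The transform is always
recomputed from the raw layer, so it is idempotent. Which analyses use
which layer is fixed: fraction scores and the membership rule use raw
counts; Wilcoxon markers, the bimod test, ulm activities, and subtype
profiles use the log layer.

## Gene-set fraction scores

A set's score in a cell is the percent of the cell's raw counts falling
in the set: `100 * sum(counts[set]) / sum(counts)`. This depends only on
within-cell fractions, so it is invariant to sequencing depth, and
scores of disjoint sets covering all genes sum to 100. It is the
quantitative substrate for quartile partitioning, signature validation
and subtype ranking.

## Supervised subtyping

Neuron subtypes are defined top-down by a curated catalog of
neuropeptide/hormone genes and their receptors: a neuron belongs to
subtype *g* exactly when its raw count for *g* is > 0. Membership is
binary and overlapping — one cell can sit in many subtypes, which is a
feature, not a bug: the overlap is itself quantified (Jaccard index)
alongside profile similarity (Pearson correlation of mean log-normalized
profiles). Both similarity readings are reported because "similarity"
between overlapping, marker-defined populations is genuinely ambiguous;
reporting the membership overlap next to the profile correlation lets a
reader see how much of the latter the former explains.

Count rankings exclude subtypes with fewer than 10 cells
(`subtype_min_cells`) in the reference group; ties are broken
alphabetically so results are deterministic. Group proportions are
weighted by each group's total neuron count, and the cross-group
relative share (the three proportions rescaled to sum to 1) is also
emitted for display.

## Quartile partition and the opposing signatures

For a pathway score over the pooled neurons, cells are sorted by score
(descending, ties broken by cell id) and cut into four contiguous
blocks whose sizes differ by at most one: c1 is the top quarter, c4 the
bottom. We use the equal-count split rather than assigning cells to
five-number-summary intervals because hinge-based intervals cannot
guarantee equal cell numbers under ties; the five-number summary of the
scores is still attached to the labels for reference.

Per quarter, positive markers are found by a one-vs-rest Wilcoxon
rank-sum test on the log layer with the usual gates (fraction expressing
≥ 0.1, Seurat-style log fold-change ≥ 0.25, BH-adjusted p < 0.05), and
genes significant in more than one quarter are discarded everywhere —
"unique" markers. Intersecting the unique c1 (resp. c4) markers across a
family of co-oriented pathway partitions yields the c1-up and c4-up
signatures. The two lists are disjoint by construction (a gene cannot be
the unique marker of two different quarters in the same partition).
Orientation matters: c1 is always the *highest*-scoring quarter, so with
metabolic pathways driving the partitions the c1-up signature tracks the
hypermetabolic (aged-like) state and c4-up the synaptic state, and their
per-cell fraction scores should correlate negatively —
`validateOpposing()` reports that correlation honestly, whichever sign
it has.

## auROC ranking and differential expression

Two-group comparisons of per-cell scores use the Mann–Whitney AUC
(`U/(n1*n2)`, ties counting one half) with a tie-corrected normal
p-value, skipping comparisons where either group has fewer than 15
cells. The AUC implementation is checked against a brute-force
all-pairs oracle, exactly, including tie halves.

Pairwise differential expression uses a 2-df likelihood-ratio test under
a zero-inflated ("bimod") model: a point mass at zero plus a normal
location model on positive log-normalized values, with the
positive-value SD pooled across groups so only the detection rate and
the positive mean differ. Genes pass pre-filters (min.pct 0.1, |logFC| ≥
0.25) before testing and a post-filter |avg_diff| > 0.1 on the
log-normalized mean difference after BH adjustment. The avg_diff scale
is the log-normalized layer; this is a documented choice, configurable
via the thresholds.

## Perturbation prioritization

How separable are two conditions within a subtype? Following the
subsampled-classifier paradigm, each subtype is scored by the mean AUC
over 50 seeded subsamples: draw 6 cells per condition without
replacement, train a random forest (100 trees, `min.node.size` 2) on
the subtype's 500 most variable genes under stratified 3-fold
cross-validation, and compute the AUC of out-of-fold condition
probabilities. Subtypes need at least 6 cells per condition. The small
node size matters: with 8 training cells per fold, the default node
size of probability forests would never split a tree and every AUC
would collapse to 0.5. Fixed subsample size (rather than proportional)
prevents abundant subtypes from winning on sample size alone. All knobs
(`augur_*`) are in the configuration.

## Rank screens and ORA

Subtypes are ranked per score set by the mean score over the subtype's
cells *in the reference group only*; top-20 and bottom-20 lists per set
are intersected, and subtypes appearing in at least 4 of the 5 lists
are reported with their hit counts. Enlarging K never removes a hit.
Over-representation analysis is the exact one-sided hypergeometric tail
with BH FDR across sets, significant at FDR < 0.05.

# The Mendelian randomization screen

Instruments are selected from the exposure summary statistics at
p < 1e-5, greedily clumped at LD r² < 0.001 when a pairwise LD table is
supplied (otherwise SNPs are assumed independent and this is logged),
and filtered by instrument strength F = (beta/se)² ≥ 10 — F exactly 10
is retained, since the rule discards instruments *below* 10.
Harmonization aligns outcome effects to the exposure effect allele,
flipping swapped records and dropping palindromic SNPs whose effect
allele frequency is within 0.08 of 0.5 (a standard tolerance; the
sources we emulate are silent on the value, so it is configurable).

Five estimators run on the Wald ratios (`beta_out / beta_exp`, first
order se `se_out / |beta_exp|`):

* **IVW** — inverse-variance-weighted mean of ratios; the standard
  error uses the multiplicative random-effects convention (fixed-effect
  se scaled by `max(1, sqrt(Q/df))`), the default of the established MR
  toolchain; a fixed-effect variant is a flag away
  (`mr_ivw_random = FALSE`).
* **MR-Egger** — weighted regression with intercept, alleles oriented
  so exposure betas are positive; the intercept tests directional
  pleiotropy. A design with constant |exposure beta| is rank-deficient
  and reported as not estimable.
* **Weighted median** — the median of the weight-cumulative ratio
  distribution; parametric bootstrap se (1000 draws, seeded).
* **Simple and weighted mode** — the mode of the kernel-smoothed ratio
  density with the `0.9 * min(sd, mad) * n^(-1/5)` bandwidth rule times
  a factor φ = 1, unweighted or inverse-variance-weighted; bootstrap
  se. When all ratios coincide, the common value is returned exactly.

Heterogeneity is Cochran's Q about the IVW estimate (χ², k − 1 df);
pleiotropy is the Egger intercept test. A direction *passes* the screen
when all five estimates share a sign (all odds ratios simultaneously
above or below 1) *and* the IVW p is below 0.05; heterogeneity and
pleiotropy only annotate the result. Running both directions
(instruments re-selected from the outcome for the reverse) classifies
the pair as forward-only, reverse-only, bidirectional or none. The
screening p-value is deliberately unadjusted across outcomes, as the
emulated design prints it; the concordance requirement already makes
the screen conservative (null pass rate well below 5%).

Bootstrap standard errors affect only the median/mode p-values, never
the estimates, the concordance signs or the IVW p — so calibration
studies can set `mr_boot_reps = 0` without changing any screening
outcome.

# The synthetic-data generator

`simulateExpression()` draws counts from a negative binomial with
shared dispersion (`variance = mu + phi mu²`, φ = 0.4) and log-normal
baseline means — the standard overdispersed scRNA-seq count model, and
the simplest law that carries a planted mean structure. On top of the
baseline:

* **Two opposing programs.** 25 "metabolic" (program A) and 25
  "synaptic" (program B) genes at base mean 2 are scaled per group
  (A: O = 3, O.T = 2, Y = 1; B reversed) and by `exp(±0.5 u)` for a
  per-cell latent activity `u ~ N(0,1)` — the plus sign for A, minus
  for B — making the programs anti-correlated within as well as between
  groups, with O.T intermediate, as the emulated aging/treatment design
  requires.
* **Subtype genes** are near-binary: in neurons a subtype gene is
  present (count ≥ 1, 1 + Poisson(0.7)) with a configured per-group
  probability, and absent elsewhere. Near-binary is the right fidelity
  because the downstream membership rule is "raw count > 0" — only
  presence matters.
* **QC violators are planted explicitly** (alternately inflated total
  UMI and inflated mitochondrial counts) rather than emergent, so
  filter counts are exactly predictable in tests.
* **No batch structure**: batch correction is out of scope, so groups
  are generated without it.

`simulateGwasPair()` plants a causal effect: exposure effects
`b ~ N(0, 0.035²)`, outcome effects `causal*b + pleiotropy`, sampling
noise with the `1/sqrt(2*maf*(1-maf)*n)` standard error, Wald
p-values, independent SNPs, non-palindromic allele pairs. The default
cohort sizes are asymmetric (exposure 50,000, outcome 20,000): with
equally powered cohorts, a genuine forward causal effect propagates
enough signal into the outcome GWAS that the *mediated* effect itself
reaches the instrument threshold, creating reverse instruments whose
ratios estimate `1/causal` — and a forward-only design would be
misclassified as bidirectional. The asymmetry keeps reverse instrument
discovery driven by outcome-specific genetics (of which this generator
has none unless pleiotropy is planted), which is what "forward-only
ground truth" means. `weak_fraction` scales the chosen fraction of
exposure effects down 20-fold, producing instruments that fail F ≥ 10.

`makeToyFixture()` is a fully deterministic (no RNG) 60-cell × 100-gene
dataset with exactly 3 high-UMI and 2 high-mito cells; a copy of its
on-disk form ships in `inst/extdata/toy/`.

What the generator does *not* emulate — ambient RNA, doublets, batch
effects, realistic gene-gene correlation beyond the two programs,
spatial structure, LD — bounds what green tests mean: they demonstrate
that the algorithms recover *planted* structure of the kind the design
assumes, not that the biology of any particular dataset satisfies those
assumptions.

# Problem sizes and numerical choices

The recovery studies run at desk scale, chosen once as the smallest
sizes at which the planted effects are comfortably identifiable:
signature recovery on 3,000 neurons × 1,500 genes through six synthetic
pathways; prioritization on 10 subtypes × ~270 neurons per group over
10 simulation seeds; MR calibration on 500 null replicates and recovery
on 200 replicates at 150 SNPs. Tie-breaking is alphabetical or by cell
id everywhere a sort occurs, so all outputs are deterministic under a
fixed seed; the pipeline runner stamps every table with a configuration
fingerprint and reruns are byte-identical. Degenerate inputs (constant
expression, zero-variance weights or features, empty intersections,
all-zero genes, rank-deficient Egger designs) return defined values
(0, NA, or empty) rather than erroring, except where the result would
be meaningless downstream (QC removing every cell, zero-total cells,
fewer than 2 instruments).

# Known limitations

* The bimod LRT uses a pooled positive-value SD and 2 df; it is a
  pragmatic screen, not a calibrated genome-wide test at tiny cell
  numbers.
* ulm activities are per-cell t-statistics from a univariate fit; they
  ignore regulon overlap and gene-gene correlation.
* The weighted-median and mode standard errors are parametric
  bootstrap; with very few instruments they are optimistic.
* Clumping requires a user-supplied LD table; no reference panel is
  contacted, so absent a table the independence assumption is the
  user's responsibility.
* The catalog-driven subtyping is only as good as the catalog; genes
  missing from the data are skipped with a message, not imputed.
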