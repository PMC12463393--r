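#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the study design the package implements: cells with
#' total UMI >= 8000 or mitochondrial percent >= 15 are excluded;
#' transcription factors are kept at mean raw counts > 0.1; correlations
#' are flagged at raw p < 0.05; auROC comparisons require >= 15 cells per
#' group; subtype count ranking requires >= 10 cells; perturbation
#' prioritization subsamples 6 cells per condition and requires >= 6
#' cells per condition; rank screens use top/bottom 20 with hits in >= 4
#' lists; differential expression uses min.pct 0.1, |logFC| >= 0.25 and
#' |avg_diff| > 0.1; Mendelian randomization uses instrument p < 1e-5,
#' clumping r2 < 0.001, F >= 10 and an IVW screening p < 0.05.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `analysisConfig`.
#' @examples
#' cfg <- analysisConfig(screen_k = 10)
#' cfg$qc_max_umi
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    qc_max_umi = 8000,
    qc_max_mito_pct = 15,
    tf_min_mean = 0.1,
    corr_p = 0.05,
    auroc_min_cells = 15,
    subtype_min_cells = 10,
    augur_subsample_size = 6,
    augur_min_cells = 6,
    augur_n_subsamples = 50,
    augur_n_trees = 100,
    augur_n_features = 500,
    augur_cv_folds = 3,
    augur_min_node = 2,
    screen_k = 20,
    screen_min_hits = 4,
    deg_min_pct = 0.1,
    deg_logfc = 0.25,
    deg_avg_diff = 0.1,
    marker_padj = 0.05,
    ora_fdr = 0.05,
    mr_instrument_p = 1e-5,
    mr_clump_r2 = 0.001,
    mr_min_f = 10,
    mr_ivw_p = 0.05,
    mr_boot_reps = 1000,
    mr_mode_phi = 1,
    mr_palindromic_eaf_tol = 0.08,
    mr_ivw_random = TRUE,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  pos <- c("qc_max_umi", "qc_max_mito_pct", "auroc_min_cells",
           "subtype_min_cells", "augur_subsample_size", "augur_min_cells",
           "screen_k", "screen_min_hits", "mr_boot_reps")
  for (f in pos) if (cfg[[f]] < 0) stop(f, " must be non-negative")
  for (f in c("corr_p", "ora_fdr", "mr_instrument_p", "mr_ivw_p")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop(f, " must lie in (0, 1]")
  }
  class(cfg) <- c("analysisConfig", "list")
  cfg
}

# FNV-1a 32-bit over a string; exact modular arithmetic via 16-bit split
# (doubles alone overflow 2^53 in the multiply). Used to stamp pipeline
# outputs with a config fingerprint.
.configHash <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_num(h, b)
    lo <- h %% 2^16
    hi <- h %/% 2^16
    # (hi*2^16 + lo) * 16777619 mod 2^32, kept within double precision
    h <- (((hi * 16777619) %% 2^16) * 2^16 + lo * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

# xor for non-negative doubles < 2^32
bitwXor_num <- function(a, b) {
  hi <- bitwXor(a %/% 2^16, b %/% 2^16)
  lo <- bitwXor(a %% 2^16, b %% 2^16)
  hi * 2^16 + lo
}

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}
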