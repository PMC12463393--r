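#' Select instrumental variables from exposure summary statistics
#'
#' Keeps SNPs with exposure p-value below `mr_instrument_p` (default
#' 1e-5), then greedily clumps in ascending-p order: a SNP is dropped
#' when its LD r-squared with any already-retained SNP is at or above
#' `mr_clump_r2` (default 0.001). When no LD table is supplied the SNPs
#' are assumed independent (logged) and selection reduces to the
#' p-filter.
#'
#' @param exposure GWAS data.frame per [readGwas()].
#' @param ldInfo optional data.frame(snp_a, snp_b, r2) of pairwise LD.
#' @param cfg an [analysisConfig()].
#' @return the selected rows of `exposure` (possibly zero rows).
#' @export
selectInstruments <- function(exposure, ldInfo = NULL,
                              cfg = analysisConfig()) {
  cand <- exposure[exposure$pval < cfg$mr_instrument_p, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$pval, cand$snp), , drop = FALSE]
  if (is.null(ldInfo)) {
    message("selectInstruments: no LD info; assuming independent SNPs")
    return(cand)
  }
  ld <- rbind(data.frame(a = ldInfo$snp_a, b = ldInfo$snp_b, r2 = ldInfo$r2),
              data.frame(a = ldInfo$snp_b, b = ldInfo$snp_a, r2 = ldInfo$r2))
  kept <- character()
  for (s in cand$snp) {
    r2 <- ld$r2[ld$a == s & ld$b %in% kept]
    if (!length(r2) || all(r2 < cfg$mr_clump_r2)) kept <- c(kept, s)
  }
  cand[cand$snp %in% kept, , drop = FALSE]
}

#' Instrument strength (F-statistic) filter
#'
#' Per-SNP `F = (beta / se)^2`; weak instruments with F below `mr_min_f`
#' (default 10) are discarded. F exactly at the bound is retained.
#'
#' @param g GWAS data.frame (exposure side).
#' @param cfg an [analysisConfig()].
#' @return `g` with an added `F` column, weak rows removed.
#' @export
computeF <- function(g, cfg = analysisConfig()) {
  if (any(g$se == 0)) stop("se must be > 0")
  g$F <- (g$beta / g$se)^2
  g[g$F >= cfg$mr_min_f, , drop = FALSE]
}

#' Harmonize outcome effects to the exposure effect allele
#'
#' Matches SNPs by identifier; outcome records whose alleles are swapped
#' relative to the exposure get their beta sign flipped and eaf
#' reflected. Palindromic SNPs (A/T or C/G) with exposure effect-allele
#' frequency within `mr_palindromic_eaf_tol` (default 0.08) of 0.5 are
#' dropped as unresolvable, as are SNPs absent from the outcome or with
#' irreconcilable allele sets (logged).
#'
#' @param exposure,outcome GWAS data.frames per [readGwas()].
#' @param cfg an [analysisConfig()].
#' @return data.frame(snp, effect_allele, other_allele, beta_exposure,
#'   se_exposure, pval_exposure, eaf_exposure, beta_outcome, se_outcome,
#'   pval_outcome) - the harmonized instrument set.
#' @export
harmonize <- function(exposure, outcome, cfg = analysisConfig()) {
  m <- match(exposure$snp, outcome$snp)
  drop_missing <- is.na(m)
  if (any(drop_missing))
    message("harmonize: ", sum(drop_missing), " SNP(s) absent from outcome")
  exposure <- exposure[!drop_missing, , drop = FALSE]
  out <- outcome[m[!drop_missing], , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- exposure$other_allele ==
    comp[exposure$effect_allele]
  ambiguous <- palindromic &
    abs(exposure$eaf - 0.5) < cfg$mr_palindromic_eaf_tol
  same <- out$effect_allele == exposure$effect_allele &
    out$other_allele == exposure$other_allele
  swapped <- out$effect_allele == exposure$other_allele &
    out$other_allele == exposure$effect_allele
  # strand flips: compare on the complemented strand
  same_flip <- comp[out$effect_allele] == exposure$effect_allele &
    comp[out$other_allele] == exposure$other_allele
  swap_flip <- comp[out$effect_allele] == exposure$other_allele &
    comp[out$other_allele] == exposure$effect_allele
  aligned <- same | (same_flip & !palindromic)
  flipped <- swapped | (swap_flip & !palindromic)
  bad <- !(aligned | flipped)
  if (any(bad))
    message("harmonize: dropping ", sum(bad),
            " SNP(s) with irreconcilable alleles")
  if (any(ambiguous))
    message("harmonize: dropping ", sum(ambiguous),
            " ambiguous palindromic SNP(s)")
  keep <- !bad & !ambiguous
  beta_out <- ifelse(flipped, -out$beta, out$beta)
  eaf_out <- ifelse(flipped, 1 - out$eaf, out$eaf)
  data.frame(snp = exposure$snp[keep],
             effect_allele = exposure$effect_allele[keep],
             other_allele = exposure$other_allele[keep],
             beta_exposure = exposure$beta[keep],
             se_exposure = exposure$se[keep],
             pval_exposure = exposure$pval[keep],
             eaf_exposure = exposure$eaf[keep],
             beta_outcome = beta_out[keep],
             se_outcome = out$se[keep],
             pval_outcome = out$pval[keep],
             eaf_outcome = eaf_out[keep],
             stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratios
#'
#' `ratio = beta_outcome / beta_exposure` with first-order standard
#' error `se_outcome / |beta_exposure|`. SNPs with zero exposure beta
#' are dropped (logged).
#'
#' @param s harmonized instrument set from [harmonize()].
#' @return `s` with `ratio` and `ratio_se` columns added.
#' @export
waldRatios <- function(s) {
  zero <- s$beta_exposure == 0
  if (any(zero)) {
    message("waldRatios: dropping ", sum(zero), " SNP(s) with zero ",
            "exposure beta")
    s <- s[!zero, , drop = FALSE]
  }
  s$ratio <- s$beta_outcome / s$beta_exposure
  s$ratio_se <- s$se_outcome / abs(s$beta_exposure)
  s
}

#' Fit the five Mendelian randomization estimators
#'
#' Inverse-variance weighting (IVW: the inverse-variance-weighted mean
#' of Wald ratios; by default with a multiplicative random-effects
#' standard error, the fixed-effect se scaled by `max(1, sqrt(Q/df))`),
#' MR-Egger (weighted regression of outcome betas on exposure betas with
#' an intercept, weights `1/se_outcome^2`, alleles oriented so exposure
#' betas are positive), the weighted median (median of the
#' weight-cumulative ratio distribution, parametric-bootstrap se), and
#' the simple and weighted mode (mode of the kernel-smoothed ratio
#' density, bandwidth `mr_mode_phi` times the 0.9 * min(sd, mad) *
#' n^(-1/5) rule on the ratios, unweighted / inverse-variance weights,
#' bootstrap se). P-values are two-sided normal (t for Egger). With
#' fewer than 3 instruments only IVW and the weighted median are
#' estimable and the result is flagged; with fewer than 2, nothing is.
#'
#' @param s instrument set from [waldRatios()] (or [harmonize()]).
#' @param cfg an [analysisConfig()]; `mr_boot_reps` (default 1000)
#'   bootstrap draws are seeded from `cfg$seed`; set it to 0 to skip
#'   bootstrap standard errors (estimates are unaffected).
#' @return data.frame(method, estimate, se, p, or, n_snp) with one row
#'   per estimable method; attribute `"heterogeneity"` holds the IVW
#'   Cochran Q (see [heterogeneityQ()]) and attribute `"egger_intercept"`
#'   the Egger intercept, se and p.
#' @export
fitFiveMethods <- function(s, cfg = analysisConfig()) {
  if (!"ratio" %in% colnames(s)) s <- waldRatios(s)
  k <- nrow(s)
  if (k < 2) stop("not estimable: fewer than 2 instruments")
  ivw <- .mrIVW(s$ratio, s$ratio_se, random = cfg$mr_ivw_random)
  het <- heterogeneityQ(s, ivw$estimate)
  fits <- list(data.frame(method = "IVW", estimate = ivw$estimate,
                          se = ivw$se, p = ivw$p, stringsAsFactors = FALSE))
  boots <- if (cfg$mr_boot_reps > 0)
    .withSeed(cfg$seed, .mrBootstrap(s, cfg)) else NULL
  wm <- .mrWeightedMedian(s$ratio, 1 / s$ratio_se^2)
  wm_se <- if (!is.null(boots)) sd(boots$wmedian) else NA_real_
  fits <- c(fits, list(data.frame(method = "weighted_median",
                                  estimate = wm, se = wm_se,
                                  p = .zp(wm, wm_se))))
  egger_int <- NULL
  if (k >= 3) {
    eg <- .mrEgger(s)
    egger_int <- eg$intercept
    fits <- c(fits, list(
      data.frame(method = "egger", estimate = eg$estimate, se = eg$se,
                 p = eg$p),
      data.frame(method = "simple_mode",
                 estimate = .mrMode(s$ratio, rep(1, k), cfg$mr_mode_phi),
                 se = if (!is.null(boots)) sd(boots$smode) else NA_real_,
                 p = NA_real_),
      data.frame(method = "weighted_mode",
                 estimate = .mrMode(s$ratio, 1 / s$ratio_se^2,
                                    cfg$mr_mode_phi),
                 se = if (!is.null(boots)) sd(boots$wmode) else NA_real_,
                 p = NA_real_)))
  } else {
    message("fitFiveMethods: only ", k, " instruments; Egger and mode ",
            "estimators not estimable")
  }
  out <- do.call(rbind, fits)
  out$p[out$method == "simple_mode"] <-
    .zp(out$estimate[out$method == "simple_mode"],
        out$se[out$method == "simple_mode"])
  out$p[out$method == "weighted_mode"] <-
    .zp(out$estimate[out$method == "weighted_mode"],
        out$se[out$method == "weighted_mode"])
  out$or <- exp(out$estimate)
  out$n_snp <- k
  attr(out, "heterogeneity") <- het
  attr(out, "egger_intercept") <- egger_int
  out
}

.zp <- function(est, se) {
  if (length(est) == 0) return(numeric())
  if (is.na(se)) return(NA_real_)
  if (se == 0) return(if (est == 0) 1 else 0)
  2 * pnorm(-abs(est / se))
}

.mrIVW <- function(ratio, ratio_se, random = TRUE) {
  w <- 1 / ratio_se^2
  est <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (random && length(ratio) > 1) {
    Q <- sum(w * (ratio - est)^2)
    se <- se * max(1, sqrt(Q / (length(ratio) - 1)))
  }
  list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)))
}

.mrEgger <- function(s) {
  # orient so exposure betas are positive
  flip <- sign(s$beta_exposure)
  bx <- abs(s$beta_exposure)
  by <- s$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / s$se_outcome^2)
  sm <- suppressWarnings(summary(fit))   # perfect fits are handled below
  co <- sm$coefficients
  if (!"bx" %in% rownames(co) || anyNA(coefficients(fit))) {
    # rank-deficient design (constant |exposure beta|): not estimable
    na <- list(estimate = NA_real_, se = NA_real_, p = NA_real_)
    return(c(na, list(intercept = na)))
  }
  infl <- min(1, sm$sigma)              # at-least-multiplicative scaling
  slope_se <- if (sm$sigma == 0) 0 else co["bx", 2] / infl
  int_se <- if (sm$sigma == 0) 0 else co["(Intercept)", 2] / infl
  df <- nrow(s) - 2
  pfun <- function(est, se) if (se == 0) (if (est == 0) 1 else 0) else
    2 * pt(-abs(est / se), df)
  list(estimate = unname(co["bx", 1]), se = slope_se,
       p = pfun(co["bx", 1], slope_se),
       intercept = list(estimate = unname(co["(Intercept)", 1]),
                        se = int_se,
                        p = pfun(co["(Intercept)", 1], int_se)))
}

# weighted median of ratios: interpolate the weight-cumulative
# distribution at one half
.mrWeightedMedian <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord] / sum(w)
  cumw <- cumsum(w) - w / 2
  if (cumw[1L] >= 0.5) return(ratio[1L])
  if (cumw[length(cumw)] <= 0.5) return(ratio[length(cumw)])
  stats::approx(cumw, ratio, xout = 0.5, ties = "ordered")$y
}

# mode of the (weighted) kernel-smoothed ratio density, Hartwig-style
# bandwidth phi * 0.9 * min(sd, mad) * n^(-1/5)
.mrMode <- function(ratio, w, phi = 1) {
  if (length(unique(ratio)) == 1L) return(ratio[1L])
  s <- 0.9 * min(sd(ratio), mad(ratio)) * length(ratio)^(-1 / 5)
  h <- max(1e-8, phi * s)
  d <- density(ratio, weights = w / sum(w), bw = h)
  d$x[which.max(d$y)]
}

# parametric bootstrap of the median/mode estimators: resample both
# betas from their sampling laws, recompute ratios and estimators
.mrBootstrap <- function(s, cfg) {
  k <- nrow(s)
  reps <- cfg$mr_boot_reps
  wmedian <- smode <- wmode <- numeric(reps)
  for (r in seq_len(reps)) {
    bx <- rnorm(k, s$beta_exposure, s$se_exposure)
    by <- rnorm(k, s$beta_outcome, s$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    ratio <- by / bx
    rse <- s$se_outcome / abs(bx)
    wmedian[r] <- .mrWeightedMedian(ratio, 1 / rse^2)
    if (k >= 3) {
      smode[r] <- .mrMode(ratio, rep(1, k), cfg$mr_mode_phi)
      wmode[r] <- .mrMode(ratio, 1 / rse^2, cfg$mr_mode_phi)
    }
  }
  list(wmedian = wmedian, smode = smode, wmode = wmode)
}

#' Cochran's Q heterogeneity of the Wald ratios about the IVW estimate
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW)^2` with `w_j = 1 / se_ratio_j^2`,
#' compared to a chi-square with k - 1 degrees of freedom.
#'
#' @param s instrument set with `ratio` / `ratio_se` columns (computed
#'   if absent).
#' @param ivwEstimate optional IVW estimate; recomputed if missing.
#' @return list(Q, df, p).
#' @export
heterogeneityQ <- function(s, ivwEstimate = NULL) {
  if (!"ratio" %in% colnames(s)) s <- waldRatios(s)
  w <- 1 / s$ratio_se^2
  if (is.null(ivwEstimate))
    ivwEstimate <- sum(w * s$ratio) / sum(w)
  Q <- sum(w * (s$ratio - ivwEstimate)^2)
  df <- nrow(s) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Screen one MR direction by the concordance rule
#'
#' The direction passes when (a) all five estimators agree in sign (all
#' odds ratios simultaneously above or below 1) and (b) the IVW p-value
#' is below `mr_ivw_p` (default 0.05). Heterogeneity (Q p < 0.05) and
#' pleiotropy (Egger intercept p < 0.05) flags are attached as
#' annotation but do not gate the pass. When fewer than five methods
#' were estimable the screen fails with reason
#' `"insufficient instruments"`.
#'
#' @param fits result of [fitFiveMethods()] (or `NULL` when the
#'   direction was not estimable).
#' @param cfg an [analysisConfig()].
#' @return list(pass, concordant, ivw_p, heterogeneity_flag,
#'   pleiotropy_flag, reason, fits).
#' @export
screenMR <- function(fits, cfg = analysisConfig()) {
  if (is.null(fits) || nrow(fits) < 5)
    return(list(pass = FALSE, concordant = NA, ivw_p = NA_real_,
                heterogeneity_flag = NA, pleiotropy_flag = NA,
                reason = "insufficient instruments", fits = fits))
  conc <- !anyNA(fits$estimate) &&
    (all(fits$estimate > 0) || all(fits$estimate < 0))
  ivw_p <- fits$p[fits$method == "IVW"]
  het <- attr(fits, "heterogeneity")
  egi <- attr(fits, "egger_intercept")
  list(pass = conc && ivw_p < cfg$mr_ivw_p,
       concordant = conc, ivw_p = ivw_p,
       heterogeneity_flag = !is.null(het) && het$p < 0.05,
       pleiotropy_flag = !is.null(egi) && egi$p < 0.05,
       reason = if (conc && ivw_p < cfg$mr_ivw_p) "pass" else
         if (!conc) "discordant" else "ivw not significant",
       fits = fits)
}

#' Classify causal direction from the two screened directions
#'
#' @param forward,reverse results of [screenMR()] for the
#'   exposure-to-outcome and outcome-to-exposure directions.
#' @return `"forward-only"`, `"reverse-only"`, `"bidirectional"` or
#'   `"none"`.
#' @export
bidirectionalClassify <- function(forward, reverse) {
  if (forward$pass && reverse$pass) "bidirectional"
  else if (forward$pass) "forward-only"
  else if (reverse$pass) "reverse-only"
  else "none"
}

#' One full MR direction: select, filter, harmonize, fit, screen
#'
#' @param exposure,outcome GWAS data.frames per [readGwas()].
#' @param ldInfo optional LD table for clumping.
#' @param cfg an [analysisConfig()].
#' @return the [screenMR()] result with the instrument set attached as
#'   `$instruments`.
#' @export
mrDirection <- function(exposure, outcome, ldInfo = NULL,
                        cfg = analysisConfig()) {
  inst <- selectInstruments(exposure, ldInfo, cfg)
  inst <- if (nrow(inst)) computeF(inst, cfg) else inst
  if (nrow(inst) < 2) {
    res <- screenMR(NULL, cfg)
    res$reason <- "insufficient instruments"
    res$instruments <- inst
    return(res)
  }
  h <- harmonize(inst, outcome, cfg)
  if (nrow(h) < 2) {
    res <- screenMR(NULL, cfg)
    res$instruments <- h
    return(res)
  }
  h <- waldRatios(h)
  res <- screenMR(fitFiveMethods(h, cfg), cfg)
  res$instruments <- h
  res
}

#' Bidirectional MR screen of an exposure / outcome pair
#'
#' Runs [mrDirection()] forward (exposure to outcome) and in reverse
#' (outcome to exposure, instruments re-selected from the outcome
#' summary statistics) and classifies the causal direction.
#'
#' @inheritParams mrDirection
#' @return list(forward, reverse, class).
#' @export
mrBidirectional <- function(exposure, outcome, ldInfo = NULL,
                            cfg = analysisConfig()) {
  fwd <- mrDirection(exposure, outcome, ldInfo, cfg)
  rev <- mrDirection(outcome, exposure, ldInfo, cfg)
  list(forward = fwd, reverse = rev,
       class = bidirectionalClassify(fwd, rev))
}
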