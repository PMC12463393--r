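cfg0 <- analysisConfig(mr_boot_reps = 0)

mkInst <- function(bx, sex, by, sey) {
  waldRatios(data.frame(beta_exposure = bx, se_exposure = sex,
                        beta_outcome = by, se_outcome = sey))
}

test_that("instrument selection applies the p-threshold and greedy clumping", {
  g <- data.frame(snp = c("s1", "s2"), effect_allele = "A",
                  other_allele = "G", beta = c(0.1, 0.05),
                  se = 0.02, pval = c(1e-6, 1e-4), eaf = 0.3, n = 1e4)
  sel <- suppressMessages(selectInstruments(g))
  expect_identical(sel$snp, "s1")
  g2 <- data.frame(snp = c("s1", "s2", "s3"), effect_allele = "A",
                   other_allele = "G", beta = 0.1, se = 0.02,
                   pval = c(1e-8, 1e-6, 1e-7), eaf = 0.3, n = 1e4)
  ld <- data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5)
  sel2 <- selectInstruments(g2, ld)
  expect_setequal(sel2$snp, c("s1", "s3"))   # s2 clumped to the better s1
  # independent SNPs: selection equals the p-filter alone
  gw <- simulateGwasPair(gwasSimConfig(n_snps = 100, seed = 2))$exposure
  expect_identical(suppressMessages(selectInstruments(gw))$snp,
                   gw$snp[order(gw$pval)][seq_len(sum(gw$pval < 1e-5))])
})

test_that("F-statistic filter keeps the boundary and drops weak instruments", {
  g <- data.frame(snp = c("a", "b", "c"), beta = c(0.1, 0.03, 0.1),
                  se = c(0.02, 0.01, 0.1 / sqrt(10)))
  out <- computeF(g)
  expect_setequal(out$snp, c("a", "c"))
  expect_equal(out$F[out$snp == "a"], 25)
  expect_equal(out$F[out$snp == "c"], 10)    # F exactly 10 is kept
  expect_false("b" %in% out$snp)             # F = 9 discarded
})

test_that("harmonization flips swapped alleles and drops ambiguous palindromes", {
  expo <- data.frame(snp = c("s1", "s2", "s3"),
                     effect_allele = c("A", "A", "C"),
                     other_allele = c("G", "T", "G"),
                     beta = 0.1, se = 0.02, pval = 1e-8,
                     eaf = c(0.3, 0.49, 0.2), n = 1e4)
  outc <- data.frame(snp = c("s1", "s2", "s3"),
                     effect_allele = c("G", "A", "C"),
                     other_allele = c("A", "T", "G"),
                     beta = c(0.2, 0.2, 0.2), se = 0.02, pval = 0.5,
                     eaf = c(0.7, 0.49, 0.2), n = 1e4)
  h <- suppressMessages(harmonize(expo, outc))
  expect_false("s2" %in% h$snp)              # palindromic, eaf near 0.5
  expect_equal(h$beta_outcome[h$snp == "s1"], -0.2)   # swapped alleles
  expect_equal(h$beta_outcome[h$snp == "s3"], 0.2)    # concordant
  # s2 kept when its frequency is far from 0.5
  expo$eaf[2] <- 0.1
  h2 <- suppressMessages(harmonize(expo, outc))
  expect_true("s2" %in% h2$snp)
})

test_that("Wald ratios follow the first-order formula", {
  s <- mkInst(bx = c(0.4, 0.5), sex = 0.01, by = c(0.2, 0),
              sey = c(0.05, 0.1))
  expect_equal(s$ratio, c(0.5, 0))
  expect_equal(s$ratio_se, c(0.125, 0.2))
  expect_message(
    out <- waldRatios(data.frame(beta_exposure = c(0, 1), se_exposure = 1,
                                 beta_outcome = 1, se_outcome = 1)),
    "zero")
  expect_identical(nrow(out), 1L)
})

test_that("IVW matches the hand inverse-variance mean; equal ses give the plain mean", {
  s <- mkInst(bx = c(1, 1), sex = 0.01, by = c(0.4, 0.8), sey = c(0.1, 0.2))
  f <- suppressMessages(fitFiveMethods(s, cfg0))
  expect_equal(f$estimate[f$method == "IVW"], 0.48)
  set.seed(2)
  s2 <- mkInst(bx = rep(1, 10), sex = 0.01, by = rnorm(10), sey = 0.1)
  expect_equal(hypoScreen:::.mrIVW(s2$ratio, s2$ratio_se)$estimate,
               mean(s2$ratio))
  # constant |exposure beta| is rank-deficient for Egger: flagged NA,
  # and a screen over such fits cannot certify concordance
  f2 <- fitFiveMethods(s2, cfg0)
  expect_true(is.na(f2$estimate[f2$method == "egger"]))
  expect_false(screenMR(f2, cfg0)$pass)
})

test_that("all methods return the common ratio under degenerate agreement", {
  s <- mkInst(bx = c(0.2, 0.4, 0.8, 1), sex = 0.01,
              by = c(0.1, 0.2, 0.4, 0.5), sey = 0.05)
  f <- fitFiveMethods(s, analysisConfig(mr_boot_reps = 50, seed = 2))
  expect_identical(nrow(f), 5L)
  expect_equal(f$estimate, rep(0.5, 5))
  expect_equal(f$or, rep(exp(0.5), 5))
  het <- attr(f, "heterogeneity")
  expect_equal(het$Q, 0)
  expect_equal(het$p, 1)
})

test_that("Cochran Q matches the two-ratio hand example and the null scale", {
  s <- mkInst(bx = c(1, 1), sex = 0.01, by = c(0, 1), sey = 1)
  q <- heterogeneityQ(s)                      # unit weights, IVW = 0.5
  expect_equal(q$Q, 0.5)
  expect_identical(q$df, 1L)
  set.seed(10)
  qdf <- replicate(300, {
    k <- 20
    s <- mkInst(bx = rep(1, k), sex = 1e-6, by = rnorm(k, 0.3, 0.05),
                sey = 0.05)
    heterogeneityQ(s)$Q / (k - 1)
  })
  expect_lt(abs(mean(qdf) - 1), 0.1)
})

test_that("estimators are sign-equivariant under outcome negation", {
  set.seed(7)
  s <- mkInst(bx = rnorm(20, 0.1, 0.02), sex = 0.01,
              by = rnorm(20, 0.05, 0.02), sey = 0.02)
  f1 <- fitFiveMethods(s, cfg0)
  s2 <- s
  s2$beta_outcome <- -s2$beta_outcome
  s2$ratio <- NULL; s2$ratio_se <- NULL
  f2 <- fitFiveMethods(s2, cfg0)
  expect_equal(f2$estimate, -f1$estimate, tolerance = 1e-8)
  expect_equal(attr(f2, "heterogeneity")$Q, attr(f1, "heterogeneity")$Q)
  expect_identical(screenMR(f1, cfg0)$concordant,
                   screenMR(f2, cfg0)$concordant)
})

test_that("the screen applies the concordance and IVW rules", {
  mkFits <- function(est, ivw_p) {
    f <- data.frame(method = c("IVW", "weighted_median", "egger",
                               "simple_mode", "weighted_mode"),
                    estimate = est, se = 0.1, p = 0.5, or = exp(est),
                    n_snp = 10)
    f$p[1] <- ivw_p
    attr(f, "heterogeneity") <- list(Q = 1, df = 9, p = 0.99)
    attr(f, "egger_intercept") <- list(estimate = 0, se = 1, p = 0.9)
    f
  }
  expect_true(screenMR(mkFits(rep(0.2, 5), 0.01))$pass)
  r <- screenMR(mkFits(c(0.2, 0.2, 0.2, 0.2, -0.1), 0.001))
  expect_false(r$pass)
  expect_identical(r$reason, "discordant")
  expect_false(screenMR(mkFits(rep(0.2, 5), 0.06))$pass)
  ins <- screenMR(NULL)
  expect_false(ins$pass)
  expect_identical(ins$reason, "insufficient instruments")
})

test_that("bidirectional classification covers the four cases", {
  p <- list(pass = TRUE); f <- list(pass = FALSE)
  expect_identical(bidirectionalClassify(p, f), "forward-only")
  expect_identical(bidirectionalClassify(f, p), "reverse-only")
  expect_identical(bidirectionalClassify(p, p), "bidirectional")
  expect_identical(bidirectionalClassify(f, f), "none")
})

test_that("fewer than three instruments limits the estimable methods", {
  s <- mkInst(bx = c(1, 1), sex = 0.01, by = c(0.4, 0.5), sey = 0.1)
  f <- suppressMessages(fitFiveMethods(s, cfg0))
  expect_setequal(f$method, c("IVW", "weighted_median"))
  expect_false(screenMR(f, cfg0)$pass)
  expect_error(fitFiveMethods(s[1, ], cfg0), "fewer than 2")
})
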