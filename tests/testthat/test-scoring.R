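test_that("fraction scores match hand computation and edge conventions", {
  counts <- matrix(c(2, 3, 5), 3, 1,
                   dimnames = list(c("g1", "g2", "g3"), "c1"))
  d <- tinyDataset(counts)
  expect_equal(unname(scoreFraction(d, c("g1", "g2"))), 50)
  expect_equal(unname(scoreFraction(d, c("g1", "g2", "g3"))), 100)
  expect_warning(s <- scoreFraction(d, "absent"), "no set member")
  expect_equal(unname(s), 0)
})

test_that("fraction scores are invariant to per-cell count scaling", {
  base <- matrix(rpois(60, 5) + 1, 6, 10)
  rownames(base) <- paste0("g", 1:6)
  d1 <- tinyDataset(base)
  d2 <- tinyDataset(base * 7L)
  expect_equal(scoreFraction(d1, c("g1", "g3")),
               scoreFraction(d2, c("g1", "g3")))
})

test_that("disjoint sets covering all genes have scores summing to 100", {
  set.seed(1)
  d <- tinyDataset(matrix(rpois(80, 3) + 1, 8, 10))
  gsc <- GeneSetCollection(list(a = paste0("g0", 1:3),
                                b = paste0("g0", 4:6),
                                c = paste0("g0", 7:8)))
  sc <- scoreCollection(d, gsc)
  expect_equal(unname(rowSums(sc)), rep(100, 10))
})

test_that("TF filter is strict at the mean-count boundary", {
  counts <- matrix(0, 3, 100)
  counts[1, 1:5] <- 1     # mean 0.05 -> dropped
  counts[2, 1:10] <- 1    # mean 0.10 -> dropped (strict >)
  counts[3, ] <- 1        # mean 1    -> kept
  counts[1, 6] <- 0; counts[3, 1] <- 2  # keep cells non-degenerate
  rownames(counts) <- c("tfA", "tfB", "tfC")
  d <- tinyDataset(counts, tf = rep(TRUE, 3))
  expect_identical(filterTFs(d), "tfC")
  expect_identical(suppressMessages(filterTFs(d, c("tfA", "nope"))),
                   character(0))
})

test_that("ulm activity matches a least-squares oracle and its symmetries", {
  # 6-gene toy: expression proportional to the weight vector
  lg <- matrix(c(5, 4, 1, 2, 1, 1), 6, 1,
               dimnames = list(paste0("g", 1:6), "c1"))
  w <- c(1, 1, 0, 0, 0, 0)
  reg <- data.frame(tf = "T1", target = c("g1", "g2"), weight = 1)
  d <- tinyDataset(matrix(1L, 6, 3, dimnames = list(paste0("g", 1:6), NULL)))
  d <- normalizeLog1p(d)
  SummarizedExperiment::assay(d, "logcounts")[, 1] <- lg[, 1]
  act <- tfActivityULM(d, reg)
  oracle <- summary(lm(lg[, 1] ~ w))$coefficients["w", "t value"]
  expect_equal(act["c01", "T1"], oracle)
  expect_gt(act["c01", "T1"], 0)
  # constant cell -> 0 (cells 2 and 3 are constant after normalization)
  expect_equal(act["c02", "T1"], 0)
  # antisymmetry under weight negation
  reg_neg <- transform(reg, weight = -weight)
  act_neg <- tfActivityULM(d, reg_neg)
  expect_equal(act_neg[, "T1"], -act[, "T1"])
  # zero-variance weights -> NA
  reg0 <- data.frame(tf = "T0", target = paste0("g", 1:6), weight = 1)
  expect_true(all(is.na(tfActivityULM(d, reg0)[, "T0"])))
  # expression exactly equal to the weight vector plus a constant:
  # perfect fit, t very large and positive
  SummarizedExperiment::assay(d, "logcounts")[, 1] <- w + 2
  perfect <- tfActivityULM(d, reg)
  expect_gt(perfect["c01", "T1"], 100)
})

test_that("correlation report flags exact linear relations", {
  x <- matrix(seq_len(20), 20, 1, dimnames = list(NULL, "a"))
  y <- cbind(b = 2 * x[, 1] + 1, c = -x[, 1])
  rep <- pairwiseCorrelation(x, y)
  expect_equal(rep$table$r[rep$table$feature_b == "b"], 1)
  expect_equal(rep$table$r[rep$table$feature_b == "c"], -1)
  expect_true(all(rep$table$significant))
  # self-correlation structure: unit diagonal handled via upper triangle
  selfrep <- pairwiseCorrelation(cbind(a = x[, 1], b = y[, 1]))
  expect_identical(nrow(selfrep$table), 1L)
})

test_that("independent features are rarely flagged and |r| stays small", {
  set.seed(11)
  n <- 400
  x <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("x", 1:50)))
  y <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("y", 1:4)))
  rep <- pairwiseCorrelation(x, y)
  expect_lt(mean(abs(rep$table$r)), 0.1)
  expect_lt(mean(rep$table$significant), 0.12)   # ~5% expected at n=200 pairs
  z <- cbind(const = rep(1, n), v = rnorm(n))
  expect_warning(rep2 <- pairwiseCorrelation(z), "zero-variance")
  expect_true(is.na(rep2$table$r[1]))
})
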