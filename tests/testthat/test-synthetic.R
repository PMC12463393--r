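test_that("identical seeds give bit-identical datasets, different seeds differ", {
  cfg <- simExpressionConfig(n_cells_per_group = c(Y = 40, O = 40, "O.T" = 40),
                             n_genes = 200, seed = 5)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$dataset, "counts")),
                   as.matrix(SummarizedExperiment::assay(b$dataset, "counts")))
  expect_identical(a$truth, b$truth)
  cfg2 <- simExpressionConfig(n_cells_per_group = c(Y = 40, O = 40, "O.T" = 40),
                              n_genes = 200, seed = 6)
  c <- simulateExpression(cfg2)
  expect_false(identical(
    as.matrix(SummarizedExperiment::assay(a$dataset, "counts")),
    as.matrix(SummarizedExperiment::assay(c$dataset, "counts"))))
})

test_that("QC violators are planted exactly, and absent when disabled", {
  cfg <- simExpressionConfig(n_cells_per_group = c(Y = 100, O = 100, "O.T" = 100),
                             n_genes = 300, qc_violator_fraction = 0.1,
                             seed = 2)
  sim <- simulateExpression(cfg)
  d <- sim$dataset
  expect_length(sim$truth$qc_violators, 30)
  bad <- totalUMI(d) >= 8000 | mitoPercent(d) >= 15
  expect_setequal(colnames(d)[bad], sim$truth$qc_violators)
  expect_true(all(totalUMI(d)[match(sim$truth$qc_umi_violators,
                                    colnames(d))] >= 8000))
  expect_true(all(mitoPercent(d)[match(sim$truth$qc_mito_violators,
                                       colnames(d))] >= 15))

  cfg0 <- simExpressionConfig(n_cells_per_group = c(Y = 100, O = 100, "O.T" = 100),
                              n_genes = 300, qc_violator_fraction = 0,
                              seed = 2)
  d0 <- simulateExpression(cfg0)$dataset
  expect_false(any(totalUMI(d0) >= 8000 | mitoPercent(d0) >= 15))
})

test_that("planted program intensities order the group means (direct oracle)", {
  cfg <- simExpressionConfig(
    n_cells_per_group = c(Y = 150, O = 150, "O.T" = 150), n_genes = 400,
    program_A_intensity = c(Y = 1, O = 3, "O.T" = 1.5),
    qc_violator_fraction = 0, seed = 9)
  sim <- simulateExpression(cfg)
  cts <- as.matrix(SummarizedExperiment::assay(sim$dataset, "counts"))
  # direct recomputation from the emitted matrix, bypassing scoreFraction
  frac <- colSums(cts[sim$truth$program_A, ]) / colSums(cts)
  m <- tapply(frac, cellGroups(sim$dataset), mean)
  expect_gt(m[["O"]], m[["O.T"]])
  expect_gt(m[["O.T"]], m[["Y"]])
})

test_that("subtype genes are near-binary, neurons-only, and recoverable", {
  cfg <- simExpressionConfig(seed = 4)
  sim <- simulateExpression(cfg)
  d <- sim$dataset
  cts <- SummarizedExperiment::assay(d, "counts")
  non_neuron <- cellTypes(d) != "Neuron"
  expect_true(all(cts[cfg$subtype_genes$gene, non_neuron] == 0))
  # membership in truth matches the >0 rule on the matrix
  for (g in c("Oxt", "Esr1")) {
    on <- colnames(d)[as.vector(cts[g, ] > 0)]
    expect_setequal(on, sim$truth$subtype_members[[g]])
  }
  # every subtype with p >= 0.2 yields at least subtype_min_cells members
  rich <- cfg$subtype_genes$gene[cfg$subtype_genes$p_Y >= 0.2]
  expect_true(all(lengths(sim$truth$subtype_members[rich]) >= 10))
})

test_that("generator rejects invalid configurations", {
  expect_error(simExpressionConfig(program_A_genes = c("X", "Y1"),
                                   program_B_genes = c("Y1")),
               "disjoint")
  expect_error(simExpressionConfig(n_genes = 10), "smaller")
  expect_error(simExpressionConfig(
    n_cells_per_group = c(Y = 10, O = 10)), "named exactly")
  expect_error(gwasSimConfig(n_exposure = 1), ">= 2")
  expect_error(gwasSimConfig(maf_range = c(0, 0.5)), "maf_range")
})

test_that("GWAS pair simulation is deterministic with valid columns", {
  cfg <- gwasSimConfig(n_snps = 50, seed = 3)
  a <- simulateGwasPair(cfg)
  b <- simulateGwasPair(cfg)
  expect_identical(a, b)
  expect_silent(validateGwas(a$exposure))
  expect_silent(validateGwas(a$outcome))
})

test_that("all-weak instruments fail the F filter downstream", {
  gw <- simulateGwasPair(gwasSimConfig(n_snps = 150, weak_fraction = 1,
                                       seed = 8))
  expect_identical(nrow(computeF(gw$exposure)), 0L)
})

test_that("toy fixture has the documented shape and byte-identical output", {
  d <- makeToyFixture()
  expect_identical(ncol(d), 60L)
  expect_lte(nrow(d), 100L)
  expect_identical(sum(totalUMI(d) >= 8000), 3L)
  expect_identical(sum(mitoPercent(d) >= 15), 2L)
  dir1 <- tempfile(); dir2 <- tempfile()
  writeCounts(makeToyFixture(), dir1)
  writeCounts(makeToyFixture(), dir2)
  for (f in c("matrix.mtx", "genes.tsv", "cells.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
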