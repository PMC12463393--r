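test_that("write/read round-trip is lossless for counts and metadata", {
  d <- makeToyFixture()
  dir <- tempfile()
  writeCounts(d, dir)
  d2 <- readCounts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                   file.path(dir, "cells.tsv"))
  expect_identical(as.matrix(SummarizedExperiment::assay(d2, "counts")),
                   as.matrix(SummarizedExperiment::assay(d, "counts")))
  expect_identical(cellGroups(d2), cellGroups(d))
  expect_identical(cellTypes(d2), cellTypes(d))
  expect_identical(isMito(d2), isMito(d))
  expect_equal(totalUMI(d2), totalUMI(d))
})

test_that("malformed inputs are rejected with informative messages", {
  d <- makeToyFixture()
  dir <- tempfile()
  writeCounts(d, dir)
  g <- read.delim(file.path(dir, "genes.tsv"))
  g$symbol[2] <- g$symbol[1]
  bad <- tempfile(fileext = ".tsv")
  write.table(g, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCounts(file.path(dir, "matrix.mtx"), bad,
                          file.path(dir, "cells.tsv")),
               "Oxt")
  cells <- read.delim(file.path(dir, "cells.tsv"))[-1, ]
  bad2 <- tempfile(fileext = ".tsv")
  write.table(cells, bad2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCounts(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"), bad2),
               "cells.tsv rows")
  expect_error(ExpressionDataset(matrix(-1, 1, 1),
                                 data.frame(cell_id = "c", group = "Y",
                                            cell_type = "Neuron"),
                                 data.frame(symbol = "g", is_mito = FALSE,
                                            is_tf = FALSE)),
               "non-negative")
})

test_that("GMT parsing dedups members, drops empty lines, keeps order", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tdesc", "S3\tdesc\tC"), p)
  expect_warning(expect_warning(gsc <- readGeneSets(p), "empty"),
                 "duplicate")
  expect_identical(names(gsc), c("S1", "S3"))
  expect_identical(gsc[["S1"]], c("A", "B"))
  writeLines(character(), p)
  expect_identical(length(readGeneSets(p)), 0L)
  writeLines(c("A\td\tx", "B\td\ty", "C\td\tz"), p)
  expect_identical(names(readGeneSets(p)), c("A", "B", "C"))
})

test_that("GMT writing round-trips a collection and a SignaturePair", {
  gsc <- GeneSetCollection(list(s1 = c("A", "B"), s2 = c("C")))
  p <- tempfile(fileext = ".gmt")
  writeGeneSets(gsc, p)
  expect_identical(geneSets(readGeneSets(p)), geneSets(gsc))
  sig <- SignaturePair(c1Up = c("A", "B"), c4Up = "C")
  writeGeneSets(sig, p)
  back <- readGeneSets(p)
  expect_identical(back[["c1_up_signature"]], c("A", "B"))
})

test_that("QC bounds are inclusive on removal and the filter is idempotent", {
  counts <- matrix(0, 2, 4)
  counts[1, ] <- c(8000, 7999, 100, 100)   # gene 1 ordinary
  counts[2, ] <- c(0, 0, 0, 18)            # gene 2 mitochondrial
  d <- tinyDataset(counts, mito = c(FALSE, TRUE))
  # cell 4: umi 118 < 8000 but mito 18/118 = 15.25% >= 15
  expect_equal(round(mitoPercent(d), 2), c(0, 0, 0, 15.25))
  kept <- suppressMessages(qcFilter(d))
  expect_identical(colnames(kept), c("c02", "c03"))
  expect_identical(S4Vectors::metadata(kept)$qc_log$n_umi, 1L)
  expect_identical(S4Vectors::metadata(kept)$qc_log$n_mito, 1L)
  again <- suppressMessages(qcFilter(kept))
  expect_identical(colnames(again), colnames(kept))
  # boundary: 7999 UMI with 14.9% mito is kept
  c2 <- matrix(c(6808, 1191), 2, 1)    # total 7999, mito 14.89%
  d2 <- tinyDataset(c2, mito = c(FALSE, TRUE))
  expect_identical(ncol(suppressMessages(qcFilter(d2))), 1L)
  # all removed -> error
  d3 <- tinyDataset(matrix(9000, 1, 2))
  expect_error(suppressMessages(qcFilter(d3)), "every cell")
})

test_that("toy fixture QC retains exactly 55 of 60 cells", {
  kept <- suppressMessages(qcFilter(makeToyFixture()))
  expect_identical(ncol(kept), 55L)
})

test_that("normalization is CP10K + log1p, idempotent on the raw layer", {
  counts <- matrix(c(1, 1, 0, 2, 3, 0), nrow = 3)  # gene 3 all-zero
  d <- tinyDataset(counts)
  d <- normalizeLog1p(d)
  lg <- SummarizedExperiment::assay(d, "logcounts")
  expect_equal(lg[1, 1], log(5001))                 # 1/2 * 1e4, log1p
  expect_equal(lg[2, 1], log(5001))
  expect_true(all(lg[3, ] == 0))
  d2 <- normalizeLog1p(d)
  expect_equal(as.matrix(SummarizedExperiment::assay(d2, "logcounts")),
               as.matrix(lg))
  dz <- tinyDataset(matrix(0, 2, 1))
  expect_error(normalizeLog1p(dz), "zero-total")
})

test_that("GWAS and catalog validators reject malformed tables", {
  gw <- simulateGwasPair(gwasSimConfig(n_snps = 5, seed = 1))$exposure
  bad <- gw; bad$se[1] <- 0
  expect_error(validateGwas(bad), "se must be")
  bad <- gw; bad$snp[2] <- bad$snp[1]
  expect_error(validateGwas(bad), "duplicated SNP")
  bad <- gw; bad$effect_allele[1] <- "N"
  expect_error(validateGwas(bad), "alleles")
  expect_error(validateSubtypeCatalog(
    data.frame(subtype = c("a", "a"), gene = c("g", "h"),
               category = "peptide")), "duplicated subtype")
  expect_error(validateSubtypeCatalog(
    data.frame(subtype = "a", gene = "g", category = "other")),
    "invalid category")
})
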