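catalog3 <- data.frame(subtype = c("Oxt", "Avp", "Crh"),
                       gene = c("Oxt", "Avp", "Crh"),
                       category = c("peptide", "peptide", "peptide"))

test_that("membership is exactly the >0 rule on neurons, overlaps allowed", {
  counts <- rbind(Oxt = c(1, 2, 0, 3, 0, 1),
                  Avp = c(0, 3, 1, 0, 0, 1),
                  Crh = c(0, 0, 0, 0, 0, 0),
                  g4  = c(5, 5, 5, 5, 5, 5))
  d <- tinyDataset(counts, cell_types = c(rep("Neuron", 5), "Astro"))
  a <- assignSubtypes(d, catalog3)
  expect_setequal(subtypeMembers(a, "Oxt"), c("c01", "c02", "c04"))
  expect_setequal(subtypeMembers(a, "Avp"), c("c02", "c03"))
  expect_identical(subtypeMembers(a, "Crh"), character(0))
  # c02 belongs to both Oxt and Avp; c06 expresses both but is not a neuron
  expect_true("c02" %in% subtypeMembers(a, "Oxt") &
                "c02" %in% subtypeMembers(a, "Avp"))
  expect_false("c06" %in% unlist(subtypeMembers(a)))
  # re-derivation from the raw matrix equals stored membership
  cts <- SummarizedExperiment::assay(d, "counts")
  neurons <- colnames(d)[cellTypes(d) == "Neuron"]
  for (s in names(a))
    expect_setequal(subtypeMembers(a, s),
                    intersect(neurons, colnames(cts)[as.vector(cts[s, ] > 0)]))
  d_empty <- tinyDataset(counts, cell_types = "Astro")
  expect_error(assignSubtypes(d_empty, catalog3), "no neurons")
})

test_that("count ranking excludes below-threshold subtypes and breaks ties alphabetically", {
  set.seed(2)
  members <- list(A = sprintf("n%02d", 1:50), B = sprintf("n%02d", 1:20),
                  C = sprintf("n%02d", 31:50), D = sprintf("n%02d", 1:9))
  a <- methods::new("SubtypeAssignment", members = members,
                    category = c(A = "peptide", B = "peptide",
                                 C = "peptide", D = "peptide"),
                    definingGene = c(A = "a", B = "b", C = "c", D = "d"),
                    neuronIds = sprintf("n%02d", 1:60),
                    neuronGroups = setNames(rep("Y", 60),
                                            sprintf("n%02d", 1:60)))
  r <- countRank(a, "Y", analysisConfig())
  expect_false("D" %in% r$subtype)               # 9 < 10
  expect_identical(r$subtype, c("A", "B", "C"))  # 50, then tie 20/20 B<C
  expect_identical(r$rank, 1:3)
  # boundary: exactly 10 cells is included
  members$D <- sprintf("n%02d", 1:10)
  a@members <- members
  expect_true("D" %in% countRank(a, "Y", analysisConfig())$subtype)
})

test_that("weighted proportions divide by per-group neuron totals", {
  groups <- setNames(rep(c("Y", "O", "O.T"), c(100, 50, 50)),
                     sprintf("n%03d", 1:200))
  a <- methods::new("SubtypeAssignment",
                    members = list(S = c(sprintf("n%03d", 1:10),     # 10 in Y
                                         sprintf("n%03d", 101:105))), # 5 in O
                    category = c(S = "peptide"),
                    definingGene = c(S = "s"),
                    neuronIds = names(groups), neuronGroups = groups)
  wp <- weightedProportions(a)
  expect_equal(wp$proportion["S", "Y"], 0.10)
  expect_equal(wp$proportion["S", "O"], 0.10)
  expect_equal(wp$proportion["S", "O.T"], 0)
  expect_equal(sum(wp$relative["S", ]), 1)
  expect_equal(unname(wp$relative["S", c("Y", "O")]), c(0.5, 0.5))
  # relative share of (0.1, 0.1, 0.2) is (0.25, 0.25, 0.5)
  expect_equal(unname(0.1 * c(1, 1, 2) / sum(0.1 * c(1, 1, 2))),
               c(0.25, 0.25, 0.5))
  # the whole-neuron "subtype" has proportion 1 in every group
  a@members <- list(All = names(groups))
  expect_equal(unname(weightedProportions(a)$proportion["All", ]),
               c(1, 1, 1))
})

test_that("similarity has unit self-values; shared members raise Jaccard", {
  sim <- simulateExpression(simExpressionConfig(
    n_cells_per_group = c(Y = 80, O = 80, "O.T" = 80), n_genes = 300,
    qc_violator_fraction = 0, seed = 6))
  d <- normalizeLog1p(sim$dataset)
  a <- assignSubtypes(d, simSubtypeCatalog(
    simExpressionConfig(n_cells_per_group = c(Y = 80, O = 80, "O.T" = 80),
                        n_genes = 300, seed = 6)))
  sm <- subtypeSimilarity(a, d)
  expect_equal(unname(diag(sm$profile)), rep(1, nrow(sm$profile)))
  expect_equal(unname(diag(sm$jaccard)), rep(1, nrow(sm$jaccard)))
  expect_equal(sm$jaccard, t(sm$jaccard))
  expect_true(all(sm$jaccard >= 0 & sm$jaccard <= 1))
  # identical member sets give Jaccard 1
  a2 <- a
  a2@members <- list(X = subtypeMembers(a, "Oxt"),
                     Y2 = subtypeMembers(a, "Oxt"))
  a2@category <- c(X = "peptide", Y2 = "peptide")
  sm2 <- subtypeSimilarity(a2, d)
  expect_equal(sm2$jaccard["X", "Y2"], 1)
})
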