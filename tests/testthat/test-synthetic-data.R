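test_that("species-tree simulation plants monophyletic clades and is seeded", {
  sim <- simulateSpeciesTree(c(kor = 6, eury = 3, dpann = 2), seed = 7)
  for (cl in unique(sim$genomes$clade))
    expect_true(isMonophyletic(sim$tree,
                               sim$genomes$id[sim$genomes$clade == cl]))
  again <- simulateSpeciesTree(c(kor = 6, eury = 3, dpann = 2), seed = 7)
  expect_identical(writeNewick(sim$tree), writeNewick(again$tree))
  # 1 taxon per clade: 3-leaf tree, clades trivially monophyletic
  tiny <- simulateSpeciesTree(c(a = 1, b = 1, c = 1), seed = 1)
  expect_length(tiny$tree$tip.label, 3L)
  expect_error(simulateSpeciesTree(c(a = 0)), ">= 1 taxon")
  expect_error(simulateSpeciesTree(c(3, 2)), "named")
})

test_that("rate-zero gene families are congruent with the species tree", {
  sim <- simulateSpeciesTree(c(kor = 5, out = 4), seed = 3)
  gf <- simulateGeneFamily(sim$tree, seed = 9)
  expect_true(all(copyCounts(gf$family) == 1L))
  expect_identical(nrow(gf$events), 0L)
  gt <- familyTree(gf$family)
  gt$tip.label <- sub("\\|1$", "", gt$tip.label)
  expect_identical(rfDistance(gt, sim$tree), 0L)
  expect_equal(sort(gt$edge.length), sort(sim$tree$edge.length),
               tolerance = 1e-9)
})

test_that("duplication counts match the closed-form branching expectation", {
  sim <- simulateSpeciesTree(c(a = 4, b = 3), seed = 5)
  rate <- 0.5
  expected <- expectedDupCount(sim$tree, rate)
  nrep <- 400
  counts <- vapply(seq_len(nrep), function(i) {
    ev <- simulateGeneFamily(sim$tree, dup = rate,
                             seed = 1000 + i)$events
    sum(ev$kind == "duplication")
  }, numeric(1))
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("transfer-free families keep a monophyletic focal clade", {
  sim <- simulateSpeciesTree(c(kor = 5, eury = 3, out = 3), seed = 11)
  focalIds <- sim$genomes$id[sim$genomes$clade == "kor"]
  for (i in 1:50) {
    fam <- simulateGeneFamily(sim$tree, dup = 0.2, loss = 0.2,
                              seed = 2000 + i)$family
    tr <- familyTree(fam)
    if (is.null(tr)) next
    gm <- sub("\\|.*$", "", tr$tip.label)
    fl <- tr$tip.label[gm %in% focalIds]
    if (length(fl) >= 2) expect_true(isMonophyletic(tr, fl))
  }
})

test_that("all-lineages-lost families come back empty, not as errors", {
  tr <- readNewick("((A:5,B:5):5,(C:5,D:5):5);")
  res <- simulateGeneFamily(tr, loss = 10, seed = 2)
  expect_true(all(copyCounts(res$family) == 0L))
  expect_null(familyTree(res$family))
})

test_that("JC69 evolution is seeded and matches its expected divergence", {
  tr <- readNewick("(A:0.05,B:0.05);")
  a1 <- evolveSequences(tr, 1000, seed = 5)
  a2 <- evolveSequences(tr, 1000, seed = 5)
  expect_identical(as.character(a1), as.character(a2))
  # expected p-distance at path length 0.1
  p <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  phat <- pDistance(a1)["A", "B"]
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1000))
  # zero branch lengths: identical sequences
  tr0 <- readNewick("(A:0,B:0);")
  s <- as.character(evolveSequences(tr0, 100, seed = 1))
  expect_identical(s[["A"]], s[["B"]])
})

test_that("planted 16S group structure hits its identity targets", {
  g <- simulate16SGroups(seed = 17)
  expect_identical(as.character(g$sequences),
                   as.character(simulate16SGroups(seed = 17)$sequences))
  idm <- clademark:::identityMatrix(g$sequences)
  same <- outer(g$groups$group, g$groups$group, "==")
  diag(same) <- NA
  intra <- mean(idm[same & !is.na(same) & upper.tri(idm)])
  inter <- mean(idm[!same & !is.na(same) & upper.tri(idm)])
  expect_lt(abs(intra - 0.98), 0.01)
  expect_lt(abs(inter - 0.88), 0.02)
  # lengths dip below 700 to exercise the length filter
  lens <- rowSums(!clademark:::isGap(clademark:::alnMatrix(g$sequences)))
  expect_true(any(lens < 700) || min(lens) >= 650)
  expect_error(simulate16SGroups(intra_identity = 0.8,
                                 inter_identity = 0.9), "infeasible")
})

test_that("read-count simulation respects the length-weighted multinomial", {
  # two genomes, equal fractions, 2x length difference -> 2x reads
  at <- simulateReadCounts(c(g1 = 0.5, g2 = 0.5),
                           c(g1 = 2e6, g2 = 1e6), 3e5, seed = 4)
  counts <- assay(at, "counts")
  expect_equal(unname(counts["g1", 1] / counts["g2", 1]), 2,
               tolerance = 0.05)
  expect_identical(sum(counts), 3e5)
  one <- simulateReadCounts(c(only = 1), c(only = 1e6), 100, seed = 1)
  expect_identical(unname(assay(one, "counts")[1, 1]), 100)
  expect_error(simulateReadCounts(c(a = 0.6, b = 0.6), c(a = 1, b = 1), 10),
               "sum to 1")
})

test_that("annotation dropout tracks completeness", {
  genomes <- data.frame(id = "m1", group = "g", completeness = 88.71)
  sig <- list(g = paste0("gene", 1:10000))
  m <- simulateAnnotationTable(genomes, sig, dropout = TRUE, seed = 6)
  rate <- mean(m["m1", ])
  se <- sqrt(0.8871 * (1 - 0.8871) / 10000)
  expect_lt(abs(rate - 0.8871), 3 * se)
  full <- simulateAnnotationTable(genomes, sig, dropout = FALSE)
  expect_true(all(full == 1L))
  expect_error(simulateAnnotationTable(
    data.frame(id = "m", group = "zz", completeness = 90), sig),
    "zz")
})
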