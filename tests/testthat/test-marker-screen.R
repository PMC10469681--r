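markerFixture <- function(seed = 31) {
  sim <- simulateSpeciesTree(c(kor = 6, eury = 3, dpann = 2, tack = 3),
                             seed = seed)
  meta <- cbind(sim$genomes,
                completeness = 92, contamination = 1,
                length_bp = 2e6)
  list(sim = sim, meta = meta)
}

test_that("completeness eligibility is a strict inequality", {
  g <- data.frame(id = c("a", "b", "c"), clade = "K",
                  completeness = c(85, 88.71, 84.9))
  expect_identical(eligibleGenomes(g, 85), "b")
  expect_identical(eligibleGenomes(g[0, ], 85), character())
  expect_error(eligibleGenomes(data.frame(id = "a"), 85), "lacks")
})

test_that("single-copy and occupancy rules follow their thresholds", {
  eligible <- paste0("g", 1:10)
  fam <- function(id, counts) GeneFamily(id, counts)
  f_multi <- fam("multi", setNames(c(2L, rep(1L, 9)), eligible))
  f_full <- fam("full", setNames(rep(1L, 10), eligible))
  f_sparse <- fam("sparse", setNames(c(rep(1L, 4), rep(0L, 6)), eligible))
  f_half <- fam("half", setNames(c(rep(1L, 5), rep(0L, 5)), eligible))
  kept <- singleCopyFamilies(list(f_multi, f_full, f_sparse, f_half),
                             eligible, occupancy_min = 0.5)
  expect_setequal(kept, c("full", "half"))   # 4/10 < 0.5 <= 5/10
  # full-occupancy reading
  expect_identical(
    singleCopyFamilies(list(f_full, f_half), eligible, occupancy_min = 1),
    "full")
  # copies in non-eligible genomes are ignored
  f_out <- fam("out", c(setNames(rep(1L, 10), eligible), other = 3L))
  expect_identical(singleCopyFamilies(list(f_out), eligible, 0.5), "out")
})

test_that("monophyly and contamination screens read the gene tree", {
  fx <- markerFixture()
  clean <- simulateGeneFamily(fx$sim$tree, family_id = "clean",
                              seed = 1)$family
  expect_identical(monophylyScreen(list(clean), fx$meta, "kor"), "clean")
  expect_identical(contaminationScreen(list(clean), fx$meta, "kor",
                                       c("eury", "dpann")), "clean")
  # a transferred focal copy nested among outgroups breaks monophyly
  disrupted <- NULL
  for (s in 1:60) {
    fam <- simulateGeneFamily(fx$sim$tree, transfer = 0.8,
                              family_id = "dis", seed = 100 + s)$family
    tr <- familyTree(fam)
    if (is.null(tr)) next
    fl <- tr$tip.label[sub("\\|.*$", "", tr$tip.label) %in%
                         fx$meta$id[fx$meta$clade == "kor"]]
    if (length(fl) >= 2 && !isMonophyletic(tr, fl)) {
      disrupted <- fam
      break
    }
  }
  expect_false(is.null(disrupted))
  expect_length(monophylyScreen(list(disrupted), fx$meta, "kor"), 0L)
  noTree <- GeneFamily("bare", c(kor_1 = 1L))
  expect_error(monophylyScreen(list(noTree), fx$meta, "kor"), "bare")
})

test_that("contamination screen agrees with the brute-force minimal side", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    tr <- randomTree(n)
    labs <- tr$tip.label
    clade <- setNames(sample(c("kor", "eury", "other"), n, replace = TRUE),
                      labs)
    if (sum(clade == "kor") < 1) next
    meta <- data.frame(id = labs, clade = unname(clade), completeness = 95)
    fam <- GeneFamily("f", setNames(rep(1L, n), labs),
                      members = labs, tree = tr)
    keep <- length(contaminationScreen(list(fam), meta, "kor", "eury")) == 1
    side <- oracleMinimalSide(tr, labs[clade == "kor"])
    expect_identical(keep, !any(clade[side] == "eury"))
  }
})

test_that("gap trimming applies the strict more-than rule", {
  # 10 sequences, one column with 1 gap (10%) removed
  aln10 <- setNames(c("A-G", rep("AAG", 9)), paste0("s", 1:10))
  tr <- trimAlignment(aln10, 0.05)
  expect_identical(tr$kept, c(1L, 3L))
  # 20 sequences, exactly 5% gaps: kept
  aln20 <- setNames(c("A-G", rep("AAG", 19)), paste0("s", 1:20))
  expect_identical(trimAlignment(aln20, 0.05)$kept, 1:3)
  gapfree <- setNames(rep("ACGT", 3), c("a", "b", "c"))
  expect_identical(trimAlignment(gapfree, 0.05)$kept, 1:4)
  allgap <- c(a = "--", b = "--")
  expect_warning(res <- trimAlignment(allgap, 0), "all columns")
  expect_length(res$kept, 0L)
})

test_that("concatenation fills absent genomes with gaps and round-trips", {
  a1 <- c(`g1|1` = "ACGTACGTAC", `g2|1` = "ACGTACGTAA")
  a2 <- setNames(rep("TTTTTGGGGGCCCCC", 2), c("g1|1", "g3|1"))
  cc <- concatenateAlignments(list(famA = a1, famB = a2),
                              c("g1", "g2", "g3"))
  expect_identical(unname(nchar(cc$alignment)), rep(25L, 3))
  expect_identical(cc$partitions$start, c(1L, 11L))
  expect_identical(cc$partitions$end, c(10L, 25L))
  expect_identical(substr(cc$alignment[["g2"]], 11, 25), strrep("-", 15))
  expect_identical(substr(cc$alignment[["g3"]], 1, 10), strrep("-", 10))
  # decomposition recovers the inputs
  blockB <- substr(cc$alignment, 11, 25)
  expect_identical(unname(blockB[c(1, 3)]), unname(a2))
  dup <- c(`g1|1` = "AAAA", `g1|2` = "AAAT")
  expect_error(concatenateAlignments(list(f = dup), "g1"), "multiple")
})

test_that("the full screen keeps clean families and reports first failures", {
  fx <- markerFixture(seed = 55)
  fams <- c(
    lapply(1:6, function(i)
      simulateGeneFamily(fx$sim$tree, family_id = sprintf("clean%02d", i),
                         seed = 300 + i)$family),
    lapply(1:6, function(i)
      simulateGeneFamily(fx$sim$tree, dup = 0.4, transfer = 0.8,
                         family_id = sprintf("dis%02d", i),
                         seed = 400 + i)$family))
  rep <- suppressMessages(runMarkerScreen(fams, fx$meta, screenConfig(
    focal = "kor", excluded = c("eury", "dpann"))))
  v <- verdicts(rep)
  expect_true(all(v$kept[startsWith(v$family, "clean")]))
  expect_true(all(v$reason[v$kept] == "kept"))
  expect_true(all(v$reason[!v$kept] %in%
                    c("multi_copy", "low_occupancy", "not_monophyletic",
                      "excluded_clade_contamination", "no_alignment",
                      "no_eligible_sequences", "all_columns_trimmed")))
  sm <- superMatrix(rep)
  expect_identical(sort(names(sm)), sort(fx$meta$id))
  expect_identical(unique(Biostrings::width(sm)),
                   max(partitionMap(rep)$end))
  # idempotent: same verdicts on a rerun
  rep2 <- suppressMessages(runMarkerScreen(fams, fx$meta, screenConfig(
    focal = "kor", excluded = c("eury", "dpann"))))
  expect_identical(verdicts(rep2), v)
  expect_warning(empty <- runMarkerScreen(list(), fx$meta, screenConfig(
    focal = "kor", excluded = "eury")), "empty report")
  expect_identical(nrow(verdicts(empty)), 0L)
})
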