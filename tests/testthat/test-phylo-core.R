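test_that("Newick parsing preserves structure and rejects malformed input", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  # unrooted iff the root has >= 3 children
  expect_false(ape::is.rooted(readNewick("(A:1,B:1,C:2);")))
  expect_true(ape::is.rooted(tr))
  expect_error(readNewick("((A,B,C"), "parse error")
  expect_error(readNewick("((A,B),C));"), "position")
  expect_error(readNewick(text = "x", file = "y"), "exactly one")
})

test_that("Newick round-trip preserves topology and branch lengths", {
  set.seed(11)
  for (i in 1:10) {
    tr <- randomTree(sample(4:15, 1))
    back <- readNewick(writeNewick(tr))
    expect_identical(rfDistance(tr, back), 0L)
    expect_lt(max(abs(sort(back$edge.length) - sort(tr$edge.length))), 1e-9)
  }
})

test_that("monophyly matches examples and handles errors", {
  tr <- readNewick("((A1,A2),(B1,B2));")
  expect_true(isMonophyletic(tr, c("A1", "A2")))
  expect_false(isMonophyletic(readNewick("((A1,B1),(A2,B2));"),
                              c("A1", "A2")))
  expect_true(isMonophyletic(tr, "A1"))                       # singleton
  expect_true(isMonophyletic(tr, c("A1", "A2", "B1", "B2")))  # full set
  expect_error(isMonophyletic(tr, c("A1", "Z9")), "Z9")
  expect_error(isMonophyletic(tr, character()), "nonempty")
})

test_that("minimal spanning side matches examples", {
  tr <- readNewick("(((A1,X),A2),(B1,B2));")
  expect_identical(minimalSpanningSide(tr, c("A1", "A2")),
                   c("A1", "A2", "X"))
  tr2 <- readNewick("((A1,A2),(B1,B2));")
  expect_identical(minimalSpanningSide(tr2, c("A1", "A2")), c("A1", "A2"))
  # no proper side contains focal leaves from both root children
  expect_identical(minimalSpanningSide(tr2, c("A1", "B1", "A2", "B2")),
                   sort(tr2$tip.label))
})

test_that("p-distance handles gaps, JC correction and saturation", {
  expect_equal(pDistance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(pDistance(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # pairwise deletion: gap columns dropped per pair
  D <- pDistance(c(a = "AC-T", b = "ACGT", c = "ACGA"))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / 3)
  jc <- pDistance(c(a = "ACGT", b = "ACGA"), correction = "JC")
  expect_equal(jc["a", "b"], -0.75 * log(1 - 4 * 0.25 / 3))
  expect_equal(round(jc["a", "b"], 4), 0.3041)
  sat <- c(a = "ACGT", b = "TGCA")
  expect_error(pDistance(sat, correction = "JC"), "0.75")
  expect_equal(pDistance(sat, correction = "JC",
                         on_saturation = "inf")["a", "b"], Inf)
  expect_error(pDistance(c(a = "--AT", b = "GC--")), "comparable")
})

test_that("p-distance agrees with ape's distance engine", {
  set.seed(3)
  tr <- randomTree(6)
  aln <- evolveSequences(tr, 500, seed = 4)
  mine <- pDistance(aln)
  apeD <- as.matrix(ape::dist.dna(ape::as.DNAbin(aln), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(mine[rownames(apeD), colnames(apeD)], apeD,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: three-point formulas
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  expect_equal(sort(ape::cophenetic.phylo(tr)[lower.tri(D)]),
               sort(D[lower.tri(D)]))
  # known 4-taxon tree: topology recovered, paths reproduce D
  tr4 <- readNewick("((A:1,B:2):1,(C:1.5,D:0.5):1);")
  D4 <- ape::cophenetic.phylo(tr4)
  got <- njTree(D4)
  expect_identical(rfDistance(got, tr4), 0L)
  expect_lt(max(abs(ape::cophenetic.phylo(got)[rownames(D4), colnames(D4)] -
                      D4)), 1e-9)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- matrix(c(0, 1, 2, 0, 0, 1, 1, 1, 0), 3, 3)
  expect_error(njTree(bad), "symmetric")
})

test_that("Robinson-Foulds distance matches the split-set definition", {
  t1 <- readNewick("((A,B),(C,D));")
  t2 <- readNewick("((A,C),(B,D));")
  expect_identical(rfDistance(t1, t1), 0L)
  expect_identical(rfDistance(t1, t2), 2L)
  expect_error(rfDistance(t1, readNewick("((A,B),(C,E));")), "leaf sets")
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    a <- randomTree(n)
    b <- a
    b$tip.label <- sample(a$tip.label)    # same leaves, shuffled
    bruteA <- treeBipartitions(a)
    bruteB <- treeBipartitions(b)
    keyed <- function(x) vapply(x, paste, character(1), collapse = "\r")
    brute <- length(setdiff(keyed(bruteA), keyed(bruteB))) +
      length(setdiff(keyed(bruteB), keyed(bruteA)))
    expect_identical(rfDistance(a, b), as.integer(brute))
  }
})

test_that("FASTA alignment round-trips through 80-column wrapped files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  aln <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 50),
                                    s2 = strrep("A-GT", 50)))
  writeFastaAlignment(aln, f)
  expect_true(all(nchar(readLines(f)) <= 80))
  back <- readFastaAlignment(f)
  expect_s4_class(back, "DNAStringSet")
  expect_identical(as.character(back), as.character(aln))
})
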