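# Tree and alignment primitives: Newick I/O, bipartitions, monophyly,
# minimal spanning sides, distances, neighbor joining, Robinson-Foulds.

#' Read a tree from a Newick string or file
#'
#' Thin, strict wrapper around [ape::read.tree()]. Quoted and plain labels
#' are supported; internal node labels are ignored on read. Missing branch
#' lengths default to 0. Malformed input raises an error that names the
#' offending position where it can be localised (unbalanced parentheses,
#' missing terminal semicolon).
#'
#' @param text A Newick string (exactly one of `text`/`file`).
#' @param file Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE),
                                    collapse = "")
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("Newick parse error at position ", which(depth < 0)[1L],
         ": unmatched ')'")
  if (length(depth) && depth[length(depth)] != 0L)
    stop("Newick parse error at position ", length(chars),
         ": ", depth[length(depth)], " unclosed '('")
  if (!grepl(";\\s*$", text))
    stop("Newick parse error at position ", nchar(text),
         ": missing terminal ';'")
  tr <- withCallingHandlers(
    ape::read.tree(text = text),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: unreadable tree")
  if (anyDuplicated(tr$tip.label))
    stop("leaf labels must be unique; duplicated: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Write a tree as a Newick string or file
#'
#' @param tree An [ape::phylo] tree.
#' @param file Optional output path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when writing to a file.
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# All edge bipartition sides of the (implicitly unrooted) tree, as the leaf
# set on the child side of each edge of `tree`.
edgeLeafSets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(tree$edge[, 2L], function(ch) sets[[ch]])
}

#' Nontrivial bipartitions of a tree
#'
#' Each bipartition is represented by its canonical side: the smaller side,
#' ties broken by the lexicographically first sorted label vector. Trivial
#' bipartitions (singleton or full-set sides) are dropped. A rooted tree is
#' treated as unrooted.
#'
#' @param tree An [ape::phylo] tree.
#' @return A list of sorted character vectors, one per nontrivial
#'   bipartition, without duplicates.
#' @export
treeBipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  sides <- edgeLeafSets(tree)
  canon <- lapply(sides, function(s) {
    s <- sort(s)
    comp <- setdiff(tips, s)
    if (length(s) < length(comp)) return(s)
    if (length(comp) < length(s)) return(comp)
    if (paste(s, collapse = "\r") <= paste(comp, collapse = "\r")) s else comp
  })
  keep <- vapply(canon, function(s)
    length(s) >= 2L && length(s) <= n - 2L, logical(1L))
  unique(canon[keep])
}

checkFocal <- function(tree, focal) {
  focal <- unique(as.character(focal))
  if (length(focal) == 0L) stop("'focal' must be nonempty")
  missing <- setdiff(focal, tree$tip.label)
  if (length(missing))
    stop("focal labels absent from tree: ", paste(missing, collapse = ", "))
  focal
}

#' Test monophyly of a leaf set on an unrooted tree
#'
#' A set is monophyletic iff it is one side of some edge bipartition of the
#' unrooted tree. Singletons and the full leaf set are trivially
#' monophyletic. Rooted input is treated as unrooted.
#'
#' @param tree An [ape::phylo] tree.
#' @param focal Character vector of leaf labels, a nonempty subset of the
#'   tree's leaves.
#' @return `TRUE` or `FALSE`.
#' @examples
#' isMonophyletic(readNewick("((A1,A2),(B1,B2));"), c("A1", "A2"))
#' @export
isMonophyletic <- function(tree, focal) {
  focal <- checkFocal(tree, focal)
  n <- length(tree$tip.label)
  if (length(focal) %in% c(1L, n)) return(TRUE)
  key <- paste(sort(focal), collapse = "\r")
  tips <- sort(tree$tip.label)
  for (s in edgeLeafSets(tree)) {
    s <- sort(s)
    if (paste(s, collapse = "\r") == key) return(TRUE)
    if (length(s) == n - length(focal) &&
        paste(setdiff(tips, s), collapse = "\r") == key) return(TRUE)
  }
  FALSE
}

#' Smallest edge-bipartition side spanning a leaf set
#'
#' Returns the smallest leaf set `S` such that `focal` is contained in `S`
#' and `S` is one side of some edge bipartition of the unrooted tree; the
#' full leaf set is returned when no proper side contains `focal`. Ties in
#' size are broken by the lexicographically first sorted label vector. This
#' operationalises "the focal sequences cluster with" other clades: any
#' non-focal leaves inside the minimal spanning side are its interlopers.
#'
#' @inheritParams isMonophyletic
#' @return Sorted character vector of leaf labels.
#' @examples
#' minimalSpanningSide(readNewick("(((A1,X),A2),(B1,B2));"), c("A1", "A2"))
#' @export
minimalSpanningSide <- function(tree, focal) {
  focal <- checkFocal(tree, focal)
  tips <- sort(tree$tip.label)
  best <- tips
  bestKey <- paste(best, collapse = "\r")
  consider <- function(s) {
    s <- sort(s)
    if (!all(focal %in% s)) return()
    key <- paste(s, collapse = "\r")
    if (length(s) < length(best) ||
        (length(s) == length(best) && key < bestKey)) {
      best <<- s; bestKey <<- key
    }
  }
  for (s in edgeLeafSets(tree)) {
    consider(s)
    consider(setdiff(tips, s))
  }
  best
}

#' Pairwise distances from an alignment
#'
#' Uncorrected p-distances with pairwise deletion: for each sequence pair,
#' columns where either sequence has a gap are ignored and the distance is
#' mismatches / compared sites. The Jukes-Cantor correction
#' \eqn{-\frac{3}{4}\log(1 - \frac{4}{3} d_p)} is available for nucleotide
#' data; saturated pairs (\eqn{d_p \ge 3/4}) raise an error by default or
#' yield `Inf`.
#'
#' @param aln Alignment (`XStringSet`, named character vector, or character
#'   matrix); at least two sequences.
#' @param correction `"none"` or `"JC"`.
#' @param on_saturation `"error"` (default) or `"inf"`, for JC-saturated
#'   pairs.
#' @return Symmetric numeric matrix with zero diagonal.
#' @examples
#' pDistance(c(a = "ACGT", b = "ACGA"))
#' @export
pDistance <- function(aln, correction = c("none", "JC"),
                      on_saturation = c("error", "inf")) {
  correction <- match.arg(correction)
  on_saturation <- match.arg(on_saturation)
  m <- alnMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least two sequences")
  gaps <- isGap(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gaps[i, ] & !gaps[j, ]
    if (!any(ok))
      stop("no comparable sites between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'")
    d <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    if (correction == "JC") {
      if (d >= 0.75) {
        if (on_saturation == "error")
          stop("JC correction undefined (p >= 0.75) for pair '",
               rownames(m)[i], "'/'", rownames(m)[j], "'")
        d <- Inf
      } else d <- -0.75 * log(1 - 4 * d / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Delegates to [ape::nj()]; negative branch lengths (possible on
#' non-additive input) are clamped to zero with a warning. On additive
#' matrices the path lengths of the result reproduce the input exactly.
#'
#' @param D Symmetric numeric matrix, zero diagonal, at least 3 taxa.
#' @return An unrooted binary [ape::phylo] tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D) || any(!is.finite(D))) stop("distance matrix has NA/Inf")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of nontrivial bipartitions, via
#' [phangorn::RF.dist()]. Both trees must share the same leaf set.
#'
#' @param t1,t2 [ape::phylo] trees on identical leaf sets.
#' @return Nonnegative integer.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Read an aligned FASTA file
#'
#' @param file Path to a FASTA file of equal-length (gapped) sequences.
#' @param type `"auto"` (default), `"DNA"` or `"AA"`.
#' @return A `Biostrings::XStringSet` of equal widths.
#' @export
readFastaAlignment <- function(file, type = c("auto", "DNA", "AA")) {
  type <- match.arg(type)
  x <- Biostrings::readBStringSet(file)
  if (length(unique(Biostrings::width(x))) > 1L)
    stop("sequences in ", file, " are not aligned (unequal lengths)")
  if (type == "auto") {
    letters <- unique(strsplit(paste(as.character(x), collapse = ""),
                               "")[[1L]])
    type <- if (all(toupper(letters) %in%
                    c("A", "C", "G", "T", "U", "N", "-", "."))) "DNA" else "AA"
  }
  if (type == "DNA") Biostrings::DNAStringSet(x)
  else Biostrings::AAStringSet(x)
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param x `XStringSet` or named character vector.
#' @param file Output path.
#' @export
writeFastaAlignment <- function(x, file) {
  if (!is(x, "XStringSet")) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, file, width = 80L)
  invisible(file)
}
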