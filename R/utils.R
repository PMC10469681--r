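# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the expression as-is.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31.
childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483399L
}

#' Coerce an alignment to an upper-case character matrix (rows = sequences)
#'
#' Accepts a `Biostrings::XStringSet`, a named character vector of equal-width
#' strings, or an already-formed character matrix with rownames.
#' @noRd
alnMatrix <- function(aln) {
  if (is(aln, "XStringSet")) {
    m <- as.matrix(aln)
  } else if (is.matrix(aln)) {
    m <- aln
  } else if (is.character(aln)) {
    if (length(aln) == 0L)
      return(matrix(character(), 0L, 0L,
                    dimnames = list(character(), NULL)))
    if (is.null(names(aln))) stop("alignment sequences must be named")
    w <- unique(nchar(aln))
    if (length(w) != 1L)
      stop("alignment sequences must all have the same length")
    m <- matrix(unlist(strsplit(aln, "", fixed = TRUE), use.names = FALSE),
                nrow = length(aln), byrow = TRUE,
                dimnames = list(names(aln), NULL))
  } else {
    stop("unsupported alignment representation: ", class(aln)[1L])
  }
  if (is.null(rownames(m))) stop("alignment sequences must be named")
  if (anyDuplicated(rownames(m))) stop("alignment labels must be unique")
  toupper(m)
}

# Character-matrix alignment back to a named character vector.
alnStrings <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

isGap <- function(x) x == "-" | x == "."

# Genome id from a gene-copy leaf label "genome|copy".
leafGenome <- function(labels) sub("\\|.*$", "", labels)
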