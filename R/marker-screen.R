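# Marker-gene curation: eligibility, single-copy/occupancy, monophyly and
# contamination screens over gene families, then gap trimming and
# concatenation into a supermatrix.

#' Screening configuration
#'
#' Thresholds for [runMarkerScreen()]. Completeness uses a strict `>`
#' comparison (a genome at exactly the threshold is excluded); occupancy
#' uses `>=` (families in fewer than `occupancy_min` of the eligible
#' genomes are discarded); gap trimming removes columns with strictly more
#' than `max_gap_frac` gaps.
#'
#' @param completeness_min Minimum genome completeness, percent (strict >).
#' @param occupancy_min Minimum fraction of eligible genomes carrying the
#'   family.
#' @param focal Focal clade label (e.g. `"Korarchaeota"`).
#' @param excluded Character vector of excluded clade labels (e.g.
#'   `c("Euryarchaeota", "DPANN")`).
#' @param max_gap_frac Maximum per-column gap fraction retained.
#' @return A named list of class `"screen_config"`.
#' @export
screenConfig <- function(completeness_min = 85, occupancy_min = 0.5,
                         focal = "Korarchaeota",
                         excluded = c("Euryarchaeota", "DPANN"),
                         max_gap_frac = 0.05) {
  stopifnot(completeness_min >= 0, completeness_min <= 100,
            occupancy_min >= 0, occupancy_min <= 1,
            max_gap_frac >= 0, max_gap_frac < 1,
            length(focal) == 1L)
  structure(list(completeness_min = completeness_min,
                 occupancy_min = occupancy_min, focal = focal,
                 excluded = excluded, max_gap_frac = max_gap_frac),
            class = "screen_config")
}

checkGenomes <- function(genomes) {
  need <- c("id", "clade", "completeness")
  miss <- setdiff(need, colnames(genomes))
  if (length(miss))
    stop("genome metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genomes$id)) stop("duplicate genome ids")
  invisible(genomes)
}

#' Genomes passing the completeness filter
#'
#' @param genomes `data.frame` with columns `id`, `clade`, `completeness`
#'   (percent), and optionally `contamination`, `length_bp`, `group`.
#' @param completeness_min Threshold in percent; strictly greater
#'   completeness is required.
#' @return Character vector of eligible genome ids.
#' @examples
#' g <- data.frame(id = c("a", "b"), clade = "K",
#'                 completeness = c(85, 88.71))
#' eligibleGenomes(g, 85)  # "b" only: 85 is not > 85
#' @export
eligibleGenomes <- function(genomes, completeness_min = 85) {
  checkGenomes(genomes)
  genomes$id[genomes$completeness > completeness_min]
}

famCounts <- function(family, eligible) {
  counts <- copyCounts(family)
  out <- setNames(integer(length(eligible)), eligible)
  hit <- intersect(names(counts), eligible)
  out[hit] <- counts[hit]
  out
}

#' Single-copy and occupancy filter
#'
#' A family is kept iff no eligible genome carries two or more copies and
#' the fraction of eligible genomes carrying at least one copy is at least
#' `occupancy_min`.
#'
#' @param families List of [GeneFamily-class] objects.
#' @param eligible Character vector of eligible genome ids (nonempty).
#' @param occupancy_min Minimum occupied fraction of eligible genomes.
#' @return Character vector of retained family ids.
#' @export
singleCopyFamilies <- function(families, eligible, occupancy_min = 0.5) {
  if (length(eligible) == 0L) stop("'eligible' must be nonempty")
  keep <- vapply(families, function(f) {
    ct <- famCounts(f, eligible)
    all(ct <= 1L) && mean(ct >= 1L) >= occupancy_min
  }, logical(1L))
  vapply(families[keep], familyId, character(1L))
}

# Focal gene-copy leaves of a family tree, via the genome -> clade map.
focalLeaves <- function(tree, genomes, focal) {
  cl <- setNames(genomes$clade, genomes$id)
  tree$tip.label[cl[leafGenome(tree$tip.label)] %in% focal]
}

#' Monophyly screen over gene trees
#'
#' A family is kept iff its focal gene copies are monophyletic in the
#' family's gene tree ([isMonophyletic()], unrooted). Families with fewer
#' than two focal leaves pass vacuously (a message notes them).
#'
#' @param families List of [GeneFamily-class] objects, each with a tree.
#' @param genomes Genome metadata (`id`, `clade`).
#' @param focal Focal clade label.
#' @return Character vector of retained family ids.
#' @export
monophylyScreen <- function(families, genomes, focal) {
  checkGenomes(genomes)
  keep <- vapply(families, function(f) {
    tr <- familyTree(f)
    if (is.null(tr))
      stop("family '", familyId(f), "' has no gene tree")
    fl <- focalLeaves(tr, genomes, focal)
    if (length(fl) < 2L) {
      message("family '", familyId(f),
              "': <2 focal leaves, monophyly passes vacuously")
      return(TRUE)
    }
    isMonophyletic(tr, fl)
  }, logical(1L))
  vapply(families[keep], familyId, character(1L))
}

#' Contamination screen via minimal spanning sides
#'
#' A family is kept iff the smallest edge-bipartition side of its gene tree
#' containing all focal copies ([minimalSpanningSide()]) contains no leaf
#' from an excluded clade — the formal reading of "the focal sequences
#' cluster with" excluded lineages. Families with no focal leaves pass.
#'
#' @inheritParams monophylyScreen
#' @param excluded Character vector of excluded clade labels.
#' @return Character vector of retained family ids.
#' @export
contaminationScreen <- function(families, genomes, focal, excluded) {
  checkGenomes(genomes)
  cl <- setNames(genomes$clade, genomes$id)
  keep <- vapply(families, function(f) {
    tr <- familyTree(f)
    if (is.null(tr))
      stop("family '", familyId(f), "' has no gene tree")
    fl <- focalLeaves(tr, genomes, focal)
    if (length(fl) == 0L) return(TRUE)
    side <- minimalSpanningSide(tr, fl)
    !any(cl[leafGenome(side)] %in% excluded)
  }, logical(1L))
  vapply(families[keep], familyId, character(1L))
}

#' Trim high-gap columns from an alignment
#'
#' A column is kept iff its gap fraction is at most `max_gap_frac`
#' (strictly greater fractions are removed); column order is preserved.
#'
#' @param aln Alignment (`XStringSet`, named character vector, or matrix).
#' @param max_gap_frac Maximum gap fraction retained (default 0.05).
#' @return List with `alignment` (same representation class as a character
#'   named vector / `XStringSet`) and `kept` (1-based indices of retained
#'   columns). An all-gap result warns and returns a zero-width alignment.
#' @examples
#' trimAlignment(c(a = "A-G", b = "ACG", c = "ACG"), 0.05)$kept
#' @export
trimAlignment <- function(aln, max_gap_frac = 0.05) {
  m <- alnMatrix(aln)
  gapFrac <- colMeans(isGap(m))
  kept <- which(gapFrac <= max_gap_frac)
  if (length(kept) == 0L)
    warning("all columns removed by gap trimming")
  trimmed <- m[, kept, drop = FALSE]
  out <- alnStrings(trimmed)
  if (is(aln, "XStringSet")) out <- Biostrings::BStringSet(out)
  list(alignment = out, kept = kept)
}

#' Concatenate per-family alignments into a supermatrix
#'
#' One row per requested genome; a genome absent from a family receives
#' all-gap filler for that family's block. Family alignment rows are
#' matched to genomes by the `genome|copy` label convention (a bare genome
#' id also matches); two rows for one genome within a family is an error
#' (single-copy violated).
#'
#' @param alignments Named list: family id -> alignment.
#' @param genome_ids Character vector of genomes forming the rows.
#' @return List with `alignment` (named character vector, one entry per
#'   genome) and `partitions` (`data.frame` `family`, `start`, `end`;
#'   1-based inclusive supermatrix column intervals).
#' @export
concatenateAlignments <- function(alignments, genome_ids) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  if (is.null(names(alignments))) stop("'alignments' must be named")
  rows <- setNames(rep("", length(genome_ids)), genome_ids)
  parts <- data.frame(family = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  at <- 0L
  for (fam in names(alignments)) {
    m <- alnMatrix(alignments[[fam]])
    w <- ncol(m)
    gm <- leafGenome(rownames(m))
    dup <- gm[duplicated(gm)]
    if (length(dup))
      stop("family '", fam, "': multiple sequences for genome(s) ",
           paste(unique(dup), collapse = ", "))
    filler <- strrep("-", w)
    block <- setNames(rep(filler, length(genome_ids)), genome_ids)
    hit <- intersect(gm, genome_ids)
    block[hit] <- alnStrings(m)[match(hit, gm)]
    rows <- paste0(rows, block)
    names(rows) <- genome_ids
    parts <- rbind(parts, data.frame(family = fam, start = at + 1L,
                                     end = at + w,
                                     stringsAsFactors = FALSE))
    at <- at + w
  }
  list(alignment = rows, partitions = parts)
}

#' Run the full marker-gene screen
#'
#' Filters are applied in a fixed order — genome eligibility, single-copy /
#' occupancy, focal monophyly, excluded-clade contamination — then each
#' surviving family's alignment is gap-trimmed and the results are
#' concatenated into a supermatrix. Each discarded family is annotated
#' with its first failing rule.
#'
#' @param families List of [GeneFamily-class] objects (with trees and
#'   alignments for the later stages).
#' @param genomes Genome metadata (`id`, `clade`, `completeness`).
#' @param config A [screenConfig()].
#' @return A [MarkerReport-class].
#' @export
runMarkerScreen <- function(families, genomes, config = screenConfig()) {
  checkGenomes(genomes)
  stopifnot(inherits(config, "screen_config"))
  ids <- vapply(families, familyId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate family ids")
  if (length(families) == 0L) {
    warning("no families supplied: empty report")
    return(new("MarkerReport",
               verdicts = data.frame(family = character(), kept = logical(),
                                     reason = character(),
                                     stringsAsFactors = FALSE),
               supermatrix = NULL,
               partitions = data.frame(family = character(),
                                       start = integer(), end = integer()),
               config = unclass(config)))
  }
  reason <- setNames(rep(NA_character_, length(ids)), ids)
  eligible <- eligibleGenomes(genomes, config$completeness_min)
  if (length(eligible) == 0L)
    stop("no genome passes the completeness filter")

  sc <- singleCopyFamilies(families, eligible, config$occupancy_min)
  for (f in families) {
    id <- familyId(f)
    if (id %in% sc) next
    ct <- famCounts(f, eligible)
    reason[id] <- if (any(ct >= 2L)) "multi_copy" else "low_occupancy"
  }
  surv <- families[ids %in% sc]

  mono <- monophylyScreen(surv, genomes, config$focal)
  reason[setdiff(vapply(surv, familyId, character(1L)), mono)] <-
    "not_monophyletic"
  surv <- surv[vapply(surv, familyId, character(1L)) %in% mono]

  cont <- contaminationScreen(surv, genomes, config$focal, config$excluded)
  reason[setdiff(vapply(surv, familyId, character(1L)), cont)] <-
    "excluded_clade_contamination"
  surv <- surv[vapply(surv, familyId, character(1L)) %in% cont]

  trimmed <- list()
  for (f in surv) {
    aln <- familyAlignment(f)
    if (is.null(aln)) {
      reason[familyId(f)] <- "no_alignment"
      next
    }
    # restrict to eligible-genome copies before trimming
    m <- alnMatrix(aln)
    m <- m[leafGenome(rownames(m)) %in% eligible, , drop = FALSE]
    if (nrow(m) == 0L) {
      reason[familyId(f)] <- "no_eligible_sequences"
      next
    }
    tr <- suppressWarnings(trimAlignment(m, config$max_gap_frac))
    if (length(tr$kept) == 0L) {
      reason[familyId(f)] <- "all_columns_trimmed"
      next
    }
    trimmed[[familyId(f)]] <- tr$alignment
  }

  verdicts <- data.frame(family = ids, kept = ids %in% names(trimmed),
                         reason = ifelse(is.na(reason[ids]), "kept",
                                         reason[ids]),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (length(trimmed) == 0L) {
    warning("no family survived the screen: no supermatrix")
    return(new("MarkerReport", verdicts = verdicts, supermatrix = NULL,
               partitions = data.frame(family = character(),
                                       start = integer(), end = integer()),
               config = unclass(config)))
  }
  cc <- concatenateAlignments(trimmed, eligible)
  new("MarkerReport", verdicts = verdicts,
      supermatrix = Biostrings::BStringSet(cc$alignment),
      partitions = cc$partitions, config = unclass(config))
}
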