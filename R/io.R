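# Plain-text interchange: copy-count and metadata TSVs, verdict tables,
# RAxML-style partition files, and JSON group models.

#' Read a family x genome copy-count TSV
#'
#' Rows are gene families, columns genome ids, cells nonnegative copy
#' counts (first column = family id).
#'
#' @param file Path to the TSV.
#' @return List of [GeneFamily-class] objects (counts only).
#' @export
readCopyCounts <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  fams <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  lapply(seq_along(fams), function(i)
    GeneFamily(fams[i], setNames(as.integer(m[i, ]), colnames(m))))
}

#' Write a family x genome copy-count TSV
#'
#' @param families List of [GeneFamily-class] objects.
#' @param genome_ids Column order; defaults to the union of count names.
#' @param file Output path.
#' @export
writeCopyCounts <- function(families, file, genome_ids = NULL) {
  if (is.null(genome_ids))
    genome_ids <- sort(unique(unlist(lapply(families, function(f)
      names(copyCounts(f))))))
  m <- t(vapply(families, function(f) {
    v <- setNames(integer(length(genome_ids)), genome_ids)
    ct <- copyCounts(f)
    hit <- intersect(names(ct), genome_ids)
    v[hit] <- ct[hit]
    v
  }, integer(length(genome_ids))))
  df <- data.frame(family = vapply(families, familyId, character(1L)), m,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read genome metadata TSV
#'
#' Expected columns: `id`, `clade` (and optionally `group`,
#' `completeness`, `contamination`, `length_bp`).
#'
#' @param file Path to the TSV.
#' @return `data.frame`.
#' @export
readGenomeMetadata <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  checkGenomes(df)
  df
}

#' Write the per-family verdict table of a marker screen
#'
#' @param report A [MarkerReport-class].
#' @param file Output TSV path.
#' @export
writeVerdicts <- function(report, file) {
  write.table(verdicts(report), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Write a partition map
#'
#' RAxML-style text (`GENE, <family> = <start>-<end>`, 1-based inclusive)
#' or JSON with the same fields.
#'
#' @param report A [MarkerReport-class] (or a partition `data.frame`).
#' @param file Output path.
#' @param format `"raxml"` or `"json"`.
#' @export
writePartitions <- function(report, file, format = c("raxml", "json")) {
  format <- match.arg(format)
  parts <- if (is(report, "MarkerReport")) partitionMap(report) else report
  if (format == "raxml") {
    writeLines(sprintf("GENE, %s = %d-%d", parts$family, parts$start,
                       parts$end), file)
  } else {
    jsonlite::write_json(parts, file, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(file)
}

#' Save / load a group model as JSON
#'
#' @param model A [GroupModel-class].
#' @param file JSON path.
#' @return `writeGroupModel` returns the path; `readGroupModel` the model.
#' @export
writeGroupModel <- function(model, file) {
  jsonlite::write_json(list(
    representatives = as.list(setNames(
      as.character(representatives(model)),
      names(representatives(model)))),
    groups = groupAssignments(model),
    thresholds = as.list(modelThresholds(model)),
    unresolved = unresolvedPairs(model)),
    file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeGroupModel
#' @export
readGroupModel <- function(file) {
  x <- jsonlite::fromJSON(file)
  new("GroupModel",
      representatives = Biostrings::BStringSet(unlist(x$representatives)),
      groups = as.data.frame(x$groups, stringsAsFactors = FALSE),
      thresholds = unlist(x$thresholds),
      unresolved = if (length(x$unresolved))
        as.data.frame(x$unresolved, stringsAsFactors = FALSE)
      else data.frame(group1 = character(), group2 = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
}
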