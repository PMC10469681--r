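# Central S4 containers.

setOldClass("phylo")

#' GeneFamily: one homolog family across genomes
#'
#' Holds per-genome copy counts, member sequences, and (optionally) the
#' family alignment and gene tree. Gene copies are labelled
#' `"<genome>|<copy>"`; tree leaves must be a subset of the member labels.
#'
#' @slot familyId Single character id.
#' @slot counts Named nonnegative integer vector (genome -> copy count).
#' @slot members Character vector of member labels (`genome|copy`).
#' @slot alignment `XStringSet` alignment of the members, or `NULL`.
#' @slot tree `ape::phylo` gene tree on (a subset of) the members, or `NULL`.
#'
#' @aliases GeneFamily
#' @exportClass GeneFamily
setClass("GeneFamily",
  representation(familyId = "character", counts = "integer",
                 members = "character", alignment = "ANY", tree = "ANY"))

setValidity("GeneFamily", function(object) {
  msg <- character()
  if (length(object@familyId) != 1L) msg <- c(msg, "familyId must be length 1")
  if (is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by genome id")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  got <- table(leafGenome(object@members))
  want <- object@counts[object@counts > 0L]
  if (length(want) != length(got) ||
      !setequal(names(want), names(got)) ||
      any(as.integer(got[names(want)]) != as.integer(want)))
    msg <- c(msg, "counts inconsistent with member labels")
  if (!is.null(object@tree)) {
    extra <- setdiff(object@tree$tip.label, object@members)
    if (length(extra))
      msg <- c(msg, paste("tree leaves not among members:",
                          paste(head(extra, 3L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneFamily
#'
#' @param familyId Family id.
#' @param counts Named integer vector of per-genome copy counts (genomes
#'   with zero copies may be present or absent).
#' @param members Member labels `genome|copy`; derived from `counts` when
#'   omitted.
#' @param alignment Optional alignment (`XStringSet` or named character).
#' @param tree Optional `ape::phylo` gene tree.
#' @return A [GeneFamily-class] object.
#' @examples
#' GeneFamily("fam1", c(g1 = 1L, g2 = 2L))
#' @export
GeneFamily <- function(familyId, counts, members = NULL, alignment = NULL,
                       tree = NULL) {
  counts <- setNames(as.integer(counts), names(counts))
  if (is.null(members)) {
    members <- unlist(lapply(names(counts)[counts > 0L], function(g)
      paste0(g, "|", seq_len(counts[[g]]))), use.names = FALSE)
    if (is.null(members)) members <- character()
  }
  if (!is.null(alignment) && !is(alignment, "XStringSet"))
    alignment <- Biostrings::BStringSet(alignment)
  new("GeneFamily", familyId = as.character(familyId), counts = counts,
      members = as.character(members), alignment = alignment, tree = tree)
}

#' MarkerReport: outcome of the full marker-gene screen
#'
#' @slot verdicts `data.frame` with columns `family`, `kept` (logical) and
#'   `reason` (the first failing rule, or `"kept"`).
#' @slot supermatrix Concatenated alignment (`XStringSet`) over the retained
#'   families, or `NULL` when nothing was retained.
#' @slot partitions `data.frame` with columns `family`, `start`, `end`
#'   (1-based inclusive column intervals of the supermatrix).
#' @slot config The [screenConfig()] list used.
#'
#' @aliases MarkerReport
#' @exportClass MarkerReport
setClass("MarkerReport",
  representation(verdicts = "data.frame", supermatrix = "ANY",
                 partitions = "data.frame", config = "list"))

setValidity("MarkerReport", function(object) {
  msg <- character()
  if (!all(c("family", "kept", "reason") %in% colnames(object@verdicts)))
    msg <- c(msg, "verdicts needs columns family, kept, reason")
  if (nrow(object@partitions) &&
      !all(c("family", "start", "end") %in% colnames(object@partitions)))
    msg <- c(msg, "partitions needs columns family, start, end")
  if (length(msg)) msg else TRUE
})

#' GroupModel: representative-based sequence group model
#'
#' Built by [delineateGroups()]; consumed by [assignToGroup()].
#'
#' @slot representatives Aligned representative sequences (`XStringSet`).
#' @slot groups `data.frame` with columns `representative`, `group`.
#' @slot thresholds Named numeric: `rep_cluster`, `intra_min`, `inter_max`.
#' @slot unresolved `data.frame` of group pairs whose cross-identity falls
#'   in the ambiguous band (columns `group1`, `group2`, `identity`).
#'
#' @aliases GroupModel
#' @exportClass GroupModel
setClass("GroupModel",
  representation(representatives = "ANY", groups = "data.frame",
                 thresholds = "numeric", unresolved = "data.frame"))

setValidity("GroupModel", function(object) {
  msg <- character()
  th <- object@thresholds
  need <- c("rep_cluster", "intra_min", "inter_max")
  if (!all(need %in% names(th))) {
    msg <- c(msg, "thresholds must name rep_cluster, intra_min, inter_max")
  } else if (!(th[["inter_max"]] < th[["intra_min"]] &&
               th[["intra_min"]] <= th[["rep_cluster"]] &&
               th[["rep_cluster"]] <= 1))
    msg <- c(msg, "need 0 < inter_max < intra_min <= rep_cluster <= 1")
  if (!all(c("representative", "group") %in% colnames(object@groups)))
    msg <- c(msg, "groups needs columns representative, group")
  if (length(msg)) msg else TRUE
})

#' AbundanceTable: mapped-read counts with genome lengths and sample totals
#'
#' A `SummarizedExperiment` with genomes as rows and samples as columns:
#' assay `"counts"` holds mapped-read counts, `rowData()$length_bp` genome
#' lengths, and `colData()$total_reads` per-sample metagenome sizes.
#'
#' @aliases AbundanceTable-class
#' @exportClass AbundanceTable
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  counts <- assay(object, "counts")
  if (any(counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (!"length_bp" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData needs length_bp")
  else if (any(rowData(object)$length_bp <= 0))
    msg <- c(msg, "genome lengths must be positive")
  if (!"total_reads" %in% colnames(colData(object)))
    msg <- c(msg, "colData needs total_reads")
  else if (any(colSums(counts) > colData(object)$total_reads))
    msg <- c(msg, "mapped reads exceed total reads in some sample")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param counts Genomes x samples matrix of mapped-read counts.
#' @param genome_lengths Named (or positionally matched) genome lengths, bp.
#' @param total_reads Per-sample total read counts.
#' @return An [AbundanceTable-class] object.
#' @examples
#' AbundanceTable(matrix(c(10L, 90L), 2, 1,
#'                       dimnames = list(c("g1", "g2"), "s1")),
#'                genome_lengths = c(g1 = 1e6, g2 = 2e6), total_reads = 200)
#' @export
AbundanceTable <- function(counts, genome_lengths, total_reads) {
  counts <- as.matrix(counts)
  if (!is.null(names(genome_lengths)))
    genome_lengths <- genome_lengths[rownames(counts)]
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length_bp = as.numeric(genome_lengths),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(total_reads = as.numeric(total_reads),
                                   row.names = colnames(counts)))
  new("AbundanceTable", se)
}
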