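# Accessor generics, methods and show() for the S4 containers.

#' @rdname GeneFamily-class
#' @param object,x An object.
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname GeneFamily-class
#' @export
setGeneric("copyCounts", function(x) standardGeneric("copyCounts"))
#' @rdname GeneFamily-class
#' @export
setGeneric("familyAlignment", function(x) standardGeneric("familyAlignment"))
#' @rdname GeneFamily-class
#' @export
setGeneric("familyTree", function(x) standardGeneric("familyTree"))
#' @rdname GeneFamily-class
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname GeneFamily-class
#' @export
setMethod("familyId", "GeneFamily", function(x) x@familyId)
#' @rdname GeneFamily-class
#' @export
setMethod("copyCounts", "GeneFamily", function(x) x@counts)
#' @rdname GeneFamily-class
#' @export
setMethod("familyAlignment", "GeneFamily", function(x) x@alignment)
#' @rdname GeneFamily-class
#' @export
setMethod("familyTree", "GeneFamily", function(x) x@tree)
#' @rdname GeneFamily-class
#' @export
setMethod("familyMembers", "GeneFamily", function(x) x@members)

setMethod("show", "GeneFamily", function(object) {
  cat("GeneFamily '", object@familyId, "': ", length(object@members),
      " copies across ", sum(object@counts > 0L), " genomes",
      if (!is.null(object@alignment)) " [aligned]" else "",
      if (!is.null(object@tree)) " [tree]" else "", "\n", sep = "")
})

#' @rdname MarkerReport-class
#' @param x An object.
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname MarkerReport-class
#' @export
setGeneric("superMatrix", function(x) standardGeneric("superMatrix"))
#' @rdname MarkerReport-class
#' @export
setGeneric("partitionMap", function(x) standardGeneric("partitionMap"))

#' @rdname MarkerReport-class
#' @export
setMethod("verdicts", "MarkerReport", function(x) x@verdicts)
#' @rdname MarkerReport-class
#' @export
setMethod("superMatrix", "MarkerReport", function(x) x@supermatrix)
#' @rdname MarkerReport-class
#' @export
setMethod("partitionMap", "MarkerReport", function(x) x@partitions)

setMethod("show", "MarkerReport", function(object) {
  v <- object@verdicts
  cat("MarkerReport: ", nrow(v), " families screened, ", sum(v$kept),
      " kept\n", sep = "")
  if (nrow(v) && any(!v$kept)) {
    tab <- table(v$reason[!v$kept])
    for (r in names(tab)) cat("  discarded (", r, "): ", tab[[r]], "\n",
                              sep = "")
  }
  if (!is.null(object@supermatrix))
    cat("  supermatrix: ", length(object@supermatrix), " genomes x ",
        unique(Biostrings::width(object@supermatrix))[1L], " columns, ",
        nrow(object@partitions), " partitions\n", sep = "")
})

#' @rdname GroupModel-class
#' @param x An object.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname GroupModel-class
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))
#' @rdname GroupModel-class
#' @export
setGeneric("modelThresholds", function(x) standardGeneric("modelThresholds"))
#' @rdname GroupModel-class
#' @export
setGeneric("unresolvedPairs", function(x) standardGeneric("unresolvedPairs"))

#' @rdname GroupModel-class
#' @export
setMethod("representatives", "GroupModel", function(x) x@representatives)
#' @rdname GroupModel-class
#' @export
setMethod("groupAssignments", "GroupModel", function(x) x@groups)
#' @rdname GroupModel-class
#' @export
setMethod("modelThresholds", "GroupModel", function(x) x@thresholds)
#' @rdname GroupModel-class
#' @export
setMethod("unresolvedPairs", "GroupModel", function(x) x@unresolved)

setMethod("show", "GroupModel", function(object) {
  cat("GroupModel: ", nrow(object@groups), " representatives in ",
      length(unique(object@groups$group)), " groups",
      if (nrow(object@unresolved)) paste0(" (", nrow(object@unresolved),
                                          " unresolved pair(s))") else "",
      "\n", sep = "")
})

#' @rdname AbundanceTable-class
#' @param x An object.
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))
#' @rdname AbundanceTable-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname AbundanceTable-class
#' @export
setMethod("genomeLengths", "AbundanceTable", function(x)
  setNames(rowData(x)$length_bp, rownames(x)))
#' @rdname AbundanceTable-class
#' @export
setMethod("totalReads", "AbundanceTable", function(x)
  setNames(colData(x)$total_reads, colnames(x)))
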