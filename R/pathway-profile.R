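# Genome gene-content profiling: pathway presence calls, antioxidant /
# oxygen-sensitivity typing, and per-genome profile tables.

#' Define a pathway for presence calling
#'
#' A pathway is called `present` when strictly more than half of its genes
#' are present; failing that, `partial` when at least `partial_min_key` of
#' its key-cluster subunits are present ("more than one subunit"); else
#' `absent`.
#'
#' @param name Pathway name.
#' @param genes Character vector of gene symbols (nonempty).
#' @param key_genes Optional key-cluster subset of `genes` (e.g. the
#'   `cdhABCDE` CODH/ACS cluster for the Wood-Ljungdahl pathway).
#' @param partial_min_key Minimum key subunits for a `partial` call.
#' @return A named list of class `"pathway_definition"`.
#' @examples
#' wl <- pathwayDefinition("WL", c("fwdB", "ftr", "mch", "mtd",
#'                                 paste0("cdh", LETTERS[1:5])),
#'                         key_genes = paste0("cdh", LETTERS[1:5]))
#' @export
pathwayDefinition <- function(name, genes, key_genes = NULL,
                              partial_min_key = 2L) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("pathway '", name, "' has no genes")
  if (!is.null(key_genes)) {
    key_genes <- as.character(key_genes)
    if (!all(key_genes %in% genes))
      stop("key_genes must be a subset of genes")
  }
  structure(list(name = as.character(name), genes = genes,
                 key_genes = key_genes,
                 partial_min_key = as.integer(partial_min_key)),
            class = "pathway_definition")
}

#' Read pathway definitions from JSON
#'
#' The JSON is an array of objects with fields `name`, `genes`, optional
#' `key_genes` and `partial_min_key`. The package ships a default set at
#' `system.file("extdata", "pathways.json", package = "clademark")`; its
#' Wood-Ljungdahl gene list is a configurable placeholder (the associated
#' gene set varies between annotation pipelines), with the `cdhABCDE` key
#' cluster fixed.
#'
#' @param file Path to a pathway definition JSON file.
#' @return List of [pathwayDefinition()] objects, named by pathway.
#' @export
readPathwayDefinitions <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(p)
    pathwayDefinition(p$name, unlist(p$genes),
                      key_genes = if (!is.null(p$key_genes))
                        unlist(p$key_genes),
                      partial_min_key = if (!is.null(p$partial_min_key))
                        p$partial_min_key else 2L))
  setNames(out, vapply(out, `[[`, character(1L), "name"))
}

#' Default antioxidant gene panel
#'
#' Superoxide reductase (`sor`), rubredoxin (`rub`), rubrerythrin (`rbr`)
#' and bacterioferritin comigratory protein 2 (`bcp2`): the core archaeal
#' oxidative-stress defence genes used for oxygen-sensitivity typing.
#'
#' @return Character vector of the four gene symbols.
#' @export
antioxidantPanel <- function() c("sor", "rub", "rbr", "bcp2")

presentGenes <- function(genome_row, genes) {
  v <- setNames(numeric(length(genes)), genes)
  hit <- intersect(names(genome_row), genes)
  v[hit] <- genome_row[hit]
  names(v)[v >= 1]
}

#' Call pathway presence for one genome
#'
#' @param genome_row Named numeric/integer vector of gene copy counts for
#'   one genome; pathway genes missing from the vector count as absent.
#' @param pathway A [pathwayDefinition()].
#' @return Ordered factor `absent < partial < present`.
#' @examples
#' wl <- pathwayDefinition("WL", c("fwdB", "ftr", "mch", "mtd",
#'                                 paste0("cdh", LETTERS[1:5])),
#'                         key_genes = paste0("cdh", LETTERS[1:5]))
#' callPathway(c(fwdB = 1, ftr = 1, mch = 1, cdhA = 1, cdhB = 1), wl)
#' @export
callPathway <- function(genome_row, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  pres <- presentGenes(genome_row, pathway$genes)
  lev <- c("absent", "partial", "present")
  call <- if (length(pres) > length(pathway$genes) / 2) "present"
  else if (!is.null(pathway$key_genes) &&
           sum(pathway$key_genes %in% pres) >= pathway$partial_min_key)
    "partial"
  else "absent"
  factor(call, levels = lev, ordered = TRUE)
}

#' Antioxidant (oxygen-sensitivity) category of one genome
#'
#' Counts how many panel genes are present: 0 of 4 is `"none-detected"`
#' (strictly-anaerobic candidate), exactly 1 `"minimal"`, 2-3 `"partial"`,
#' all 4 `"full"`.
#'
#' @param genome_row Named copy-count vector for one genome.
#' @param panel Character vector of panel gene symbols.
#' @return List with `category` (ordered factor) and `present` (character
#'   vector of detected panel genes).
#' @export
antioxidantProfile <- function(genome_row, panel = antioxidantPanel()) {
  pres <- presentGenes(genome_row, panel)
  lev <- c("none-detected", "minimal", "partial", "full")
  category <- if (length(pres) == 0L) "none-detected"
  else if (length(pres) == 1L) "minimal"
  else if (length(pres) < length(panel)) "partial"
  else "full"
  list(category = factor(category, levels = lev, ordered = TRUE),
       present = pres)
}

#' Profile a presence matrix against pathways and the antioxidant panel
#'
#' @param matrix Genomes x gene-symbols copy-count matrix (a presence
#'   matrix as from [simulateAnnotationTable()]). Pathway genes absent from
#'   the matrix count as 0 (a message lists them once).
#' @param pathways List of [pathwayDefinition()] objects.
#' @param panel Antioxidant panel gene symbols.
#' @return `data.frame`: one row per genome with one column per pathway
#'   call, `antioxidant` category and `antioxidant_genes` (comma-joined).
#' @export
profileMatrix <- function(matrix, pathways, panel = antioxidantPanel()) {
  if (anyDuplicated(rownames(matrix))) stop("duplicate genome ids")
  if (nrow(matrix) == 0L) {
    out <- data.frame(genome = character(), stringsAsFactors = FALSE)
    return(out)
  }
  wanted <- unique(c(unlist(lapply(pathways, `[[`, "genes")), panel))
  missing <- setdiff(wanted, colnames(matrix))
  if (length(missing))
    message("genes never annotated (counted absent): ",
            paste(missing, collapse = ", "))
  rows <- lapply(rownames(matrix), function(g) {
    v <- matrix[g, ]
    calls <- vapply(pathways, function(p)
      as.character(callPathway(v, p)), character(1L))
    ao <- antioxidantProfile(v, panel)
    cbind(data.frame(genome = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(calls, vapply(pathways, `[[`,
                                                       character(1L),
                                                       "name")))),
          data.frame(antioxidant = as.character(ao$category),
                     antioxidant_genes = paste(ao$present, collapse = ","),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
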