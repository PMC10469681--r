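# 16S-style group delineation: length filter, greedy centroid clustering at
# a representative threshold, intra/inter identity group delineation, and
# query assignment.

ungappedLength <- function(aln) {
  m <- alnMatrix(aln)
  setNames(rowSums(!isGap(m)), rownames(m))
}

#' Filter sequences by ungapped length
#'
#' Sequences strictly shorter than `min_len` ungapped characters are
#' excluded (a 700 bp sequence is kept at the default cutoff).
#'
#' @param seqs Alignment or sequence set (`XStringSet`, named character
#'   vector, or character matrix); gaps do not count towards length.
#' @param min_len Minimum ungapped length in bp.
#' @return The retained subset, same representation as the input.
#' @export
lengthFilter <- function(seqs, min_len = 700) {
  keep <- ungappedLength(seqs) >= min_len
  if (is.matrix(seqs)) return(seqs[keep, , drop = FALSE])
  seqs[keep]
}

#' Pairwise identity on aligned sequences
#'
#' Matches divided by the number of columns where neither sequence has a
#' gap; terminal-gap columns are thereby excluded as well. Both sequences
#' must be rows of a common alignment.
#'
#' @param a,b Aligned sequences: single-element `XStringSet` / character,
#'   of equal width.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACGT-", "ACGA-")  # 3/4
#' @export
pairwiseIdentity <- function(a, b) {
  av <- strsplit(toupper(as.character(a)[1L]), "")[[1L]]
  bv <- strsplit(toupper(as.character(b)[1L]), "")[[1L]]
  if (length(av) != length(bv))
    stop("sequences are not rows of a common alignment (unequal widths)")
  ok <- !isGap(av) & !isGap(bv)
  if (!any(ok)) stop("zero comparable columns between the pair")
  sum(av[ok] == bv[ok]) / sum(ok)
}

# Full identity matrix for an alignment (rows x rows).
identityMatrix <- function(aln) {
  m <- alnMatrix(aln)
  n <- nrow(m)
  gaps <- isGap(m)
  out <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    ok <- !gaps[i, ] & !gaps[j, ]
    if (!any(ok))
      stop("zero comparable columns between '", rownames(m)[i], "' and '",
           rownames(m)[j], "'")
    out[i, j] <- out[j, i] <- sum(m[i, ok] == m[j, ok]) / sum(ok)
  }
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in order of decreasing ungapped length (ties:
#' lexicographic id). Each sequence joins the first existing centroid with
#' identity at least `threshold`, else founds a new cluster. Every member
#' therefore has identity >= `threshold` to its centroid.
#'
#' @param seqs Aligned sequences (`XStringSet` or named character vector).
#' @param threshold Identity threshold (default 0.99, the usual
#'   representative-sequence cutoff).
#' @return `data.frame` with columns `member`, `centroid`.
#' @export
greedyCluster <- function(seqs, threshold = 0.99) {
  m <- alnMatrix(seqs)
  if (nrow(m) == 0L) stop("need at least one sequence")
  len <- rowSums(!isGap(m))
  ord <- order(-len, rownames(m), method = "radix")
  centroids <- character()
  assign <- character(nrow(m))
  names(assign) <- rownames(m)[ord]
  for (id in rownames(m)[ord]) {
    hit <- NA_character_
    for (ce in centroids) {
      ok <- !isGap(m[id, ]) & !isGap(m[ce, ])
      if (!any(ok)) next
      if (sum(m[id, ok] == m[ce, ok]) / sum(ok) >= threshold) {
        hit <- ce
        break
      }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      hit <- id
    }
    assign[id] <- hit
  }
  data.frame(member = names(assign), centroid = unname(assign),
             stringsAsFactors = FALSE)
}

#' Delineate groups among representative sequences
#'
#' Representatives are linked when their identity strictly exceeds
#' `intra_min`; groups are the connected components of that graph
#' (singletons form singleton groups). Any cross-group pair whose identity
#' is at least `inter_max` — i.e. inside the ambiguous band between the
#' inter- and intra-group thresholds — is flagged unresolved rather than
#' merged.
#'
#' @param reps Aligned representative sequences.
#' @param intra_min Within-group identity threshold (default 0.97).
#' @param inter_max Between-group identity ceiling (default 0.91).
#' @param rep_cluster Representative-clustering threshold recorded in the
#'   model (default 0.99).
#' @return A [GroupModel-class]; groups are labelled `"grp1"`, `"grp2"`,
#'   ... in order of first representative (sorted ids), so the labelling is
#'   invariant to input order.
#' @export
delineateGroups <- function(reps, intra_min = 0.97, inter_max = 0.91,
                            rep_cluster = 0.99) {
  m <- alnMatrix(reps)
  m <- m[order(rownames(m)), , drop = FALSE]     # input-order invariance
  n <- nrow(m)
  if (n == 0L) stop("need at least one representative")
  idm <- identityMatrix(m)
  adj <- idm > intra_min
  diag(adj) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  grp <- paste0("grp", comp$membership)
  names(grp) <- rownames(m)
  unresolved <- data.frame(group1 = character(), group2 = character(),
                           identity = numeric(), stringsAsFactors = FALSE)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (grp[i] != grp[j] && idm[i, j] >= inter_max) {
      g1 <- sort(c(grp[[i]], grp[[j]]))
      k <- which(unresolved$group1 == g1[1L] & unresolved$group2 == g1[2L])
      if (length(k)) {
        unresolved$identity[k] <- max(unresolved$identity[k], idm[i, j])
      } else {
        unresolved <- rbind(unresolved,
                            data.frame(group1 = g1[1L], group2 = g1[2L],
                                       identity = idm[i, j],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  seqs <- alnStrings(m)
  new("GroupModel",
      representatives = Biostrings::BStringSet(seqs),
      groups = data.frame(representative = rownames(m), group = unname(grp),
                          stringsAsFactors = FALSE),
      thresholds = c(rep_cluster = rep_cluster, intra_min = intra_min,
                     inter_max = inter_max),
      unresolved = unresolved)
}

#' Assign query sequences to delineated groups
#'
#' Each query is compared to every representative (aligned-column
#' identity); it is assigned the best hit's group when that identity
#' strictly exceeds the model's `intra_min`, else `"unassigned"`.
#'
#' @param query Aligned query sequence(s), same column space as the model's
#'   representatives.
#' @param model A [GroupModel-class].
#' @return `data.frame` with columns `query`, `group`, `best_identity`,
#'   `best_representative`.
#' @export
assignToGroup <- function(query, model) {
  qm <- alnMatrix(query)
  reps <- alnMatrix(representatives(model))
  if (ncol(qm) != ncol(reps))
    stop("query alignment width differs from the model's")
  g <- setNames(groupAssignments(model)$group,
                groupAssignments(model)$representative)
  intra <- modelThresholds(model)[["intra_min"]]
  out <- lapply(rownames(qm), function(id) {
    ident <- vapply(rownames(reps), function(r) {
      ok <- !isGap(qm[id, ]) & !isGap(reps[r, ])
      if (!any(ok)) return(NA_real_)
      sum(qm[id, ok] == reps[r, ok]) / sum(ok)
    }, numeric(1L))
    best <- which.max(ident)
    data.frame(query = id,
               group = if (is.finite(ident[best]) && ident[best] > intra)
                 g[[rownames(reps)[best]]] else "unassigned",
               best_identity = unname(ident[best]),
               best_representative = rownames(reps)[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
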