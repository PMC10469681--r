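# Seeded generators for every input the pipeline consumes, each with
# planted ground truth: species trees with labelled clades, gene families
# evolving with duplication/transfer/loss, JC69 sequence evolution,
# group-structured 16S-style sequence sets, annotation matrices with
# completeness-driven dropout, and multinomial read counts.

treeHeight <- function(tree) max(ape::node.depth.edgelength(tree))

# Ultrametric Yule clade of n >= 2 tips rescaled to a given height.
yuleClade <- function(n, birth, height, labels) {
  tr <- ape::rphylo(n, birth = birth, death = 0)
  tr$tip.label <- labels
  h <- treeHeight(tr)
  if (h > 0) tr$edge.length <- tr$edge.length * (height / h)
  tr
}

rxEscape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Simulate a species tree with labelled, monophyletic clades
#'
#' Builds a Yule backbone over the named clades and grafts an independent
#' Yule radiation for each clade at the corresponding backbone tip, so every
#' named clade is monophyletic by construction. Branch lengths are in
#' expected substitutions per site; the tree is rescaled so the root-to-tip
#' depth is `depth`.
#'
#' @param clades Named list/vector: clade name -> number of taxa (>= 1).
#'   Taxa are labelled `"<clade>_<i>"`.
#' @param birth Yule birth rate (events per lineage per unit time).
#' @param depth Root-to-tip depth of the final tree, substitutions/site.
#' @param clade_height_frac Fraction of a clade's backbone pendant branch
#'   converted into its internal radiation (0 < frac < 1).
#' @param seed Optional integer seed; the result is bit-reproducible.
#' @return List with elements `tree` (rooted binary [ape::phylo]) and
#'   `genomes` (`data.frame` with columns `id`, `clade`).
#' @examples
#' sim <- simulateSpeciesTree(c(kor = 4, eury = 2, dpann = 2), seed = 1)
#' isMonophyletic(sim$tree, sim$genomes$id[sim$genomes$clade == "kor"])
#' @export
simulateSpeciesTree <- function(clades, birth = 1, depth = 0.75,
                                clade_height_frac = 0.5, seed = NULL) {
  clades <- unlist(clades)
  if (length(clades) < 1L || any(clades < 1L))
    stop("each named clade needs >= 1 taxon")
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("clades must be named")
  if (birth <= 0 || depth <= 0) stop("rates and depth must be positive")
  if (clade_height_frac <= 0 || clade_height_frac >= 1)
    stop("clade_height_frac must be in (0, 1)")
  withSeed(seed, {
    labels <- lapply(names(clades), function(cl)
      paste0(cl, "_", seq_len(clades[[cl]])))
    names(labels) <- names(clades)
    k <- length(clades)
    if (k == 1L) {
      cl <- names(clades)
      tr <- if (clades[[cl]] == 1L)
        readNewick(paste0("(", labels[[cl]], ":", depth, ");"))
      else yuleClade(clades[[cl]], birth, depth, labels[[cl]])
    } else {
      backbone <- yuleClade(k, birth, depth, names(clades))
      pend <- backbone$edge.length[match(seq_len(k), backbone$edge[, 2L])]
      nwk <- writeNewick(backbone)
      for (ci in seq_len(k)) {
        cl <- backbone$tip.label[ci]
        n <- clades[[cl]]
        if (n == 1L) {
          graft <- labels[[cl]]
          newPend <- pend[ci]
        } else {
          hsub <- clade_height_frac * pend[ci]
          cladeTr <- yuleClade(n, birth, hsub, labels[[cl]])
          graft <- base::sub(";$", "", writeNewick(cladeTr))
          newPend <- pend[ci] - hsub
        }
        # a tip label in Newick is always preceded by '(' or ','
        nwk <- base::sub(paste0("(?<=[(,])", rxEscape(cl), ":"),
                         paste0(graft, ":@"), nwk, perl = TRUE)
        nwk <- base::sub("@[0-9.eE+-]+", sprintf("%.10g", newPend), nwk)
      }
      tr <- readNewick(nwk)
    }
    genomes <- data.frame(
      id = unlist(labels, use.names = FALSE),
      clade = rep(names(clades), clades),
      stringsAsFactors = FALSE)
    list(tree = tr, genomes = genomes)
  })
}

nodeNewick <- function(node) {
  if (is.null(node$children))
    paste0(node$label, ":", sprintf("%.10g", node$len))
  else
    paste0("(", paste(vapply(node$children, nodeNewick, character(1L)),
                      collapse = ","),
           "):", sprintf("%.10g", node$len))
}

countLeaves <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, countLeaves, integer(1L)))
}

#' Simulate a gene family along a species tree with duplication,
#' transfer and loss
#'
#' A single gene lineage enters the species tree at its root and traverses
#' species branches. Along a branch, events occur at total rate
#' `dup + transfer + loss` per branch-length unit: a duplication splits the
#' lineage in place, a transfer copies it to the top of a uniformly chosen
#' other species branch (the undated fallback: the tree carries no time
#' calibration), and a loss terminates it. Lineages reaching species tips
#' become gene copies labelled `"<genome>|<copy>"`. Sequences are evolved
#' under JC69 along the resulting gene tree.
#'
#' With all rates 0 the gene tree is congruent with the species tree
#' (identical topology and branch lengths, leaves `"<genome>|1"`).
#'
#' @param species_tree Rooted [ape::phylo] with branch lengths
#'   (substitutions/site).
#' @param dup,transfer,loss Event rates per branch-length unit (>= 0).
#' @param n_sites Sequence length in sites.
#' @param family_id Family id for the returned [GeneFamily-class].
#' @param seed Optional integer seed.
#' @param max_events Safety cap on simulated events.
#' @return List with elements `family` (a [GeneFamily-class]; empty family
#'   when every lineage was lost) and `events` (`data.frame` with columns
#'   `kind`, `donor_edge`, `recipient_edge`, `position`).
#' @export
simulateGeneFamily <- function(species_tree, dup = 0, transfer = 0,
                               loss = 0, n_sites = 300L, family_id = "fam1",
                               seed = NULL, max_events = 10000L) {
  stopifnot(dup >= 0, transfer >= 0, loss >= 0, n_sites >= 1L)
  if (is.null(species_tree$edge.length))
    stop("species tree needs branch lengths")
  withSeed(seed, {
    ntip <- length(species_tree$tip.label)
    edge <- species_tree$edge
    elen <- species_tree$edge.length
    nedge <- nrow(edge)
    childEdges <- split(seq_len(nedge), edge[, 1L])
    rate <- dup + transfer + loss
    events <- list()
    nEvents <- 0L
    copyN <- new.env(parent = emptyenv())

    leafNode <- function(tip, len) {
      g <- species_tree$tip.label[tip]
      k <- (if (is.null(copyN[[g]])) 0L else copyN[[g]]) + 1L
      copyN[[g]] <- k
      list(label = paste0(g, "|", k), len = len, children = NULL)
    }
    combine <- function(kids, len) {
      kids <- kids[!vapply(kids, is.null, logical(1L))]
      if (length(kids) == 0L) return(NULL)
      if (length(kids) == 1L) {
        kids[[1L]]$len <- kids[[1L]]$len + len
        return(kids[[1L]])
      }
      list(label = NULL, len = len, children = kids)
    }
    simFromEdge <- function(e, pos) {
      L <- elen[e]
      w <- if (rate > 0) rexp(1L, rate) else Inf
      if (pos + w < L) {
        nEvents <<- nEvents + 1L
        if (nEvents > max_events)
          stop("event cap exceeded (", max_events, "); lower the rates")
        at <- pos + w
        kind <- sample(c("duplication", "transfer", "loss"), 1L,
                       prob = c(dup, transfer, loss))
        if (kind == "loss") {
          events[[nEvents]] <<- data.frame(kind = kind, donor_edge = e,
                                           recipient_edge = NA_integer_,
                                           position = at)
          return(NULL)
        }
        if (kind == "duplication") {
          events[[nEvents]] <<- data.frame(kind = kind, donor_edge = e,
                                           recipient_edge = NA_integer_,
                                           position = at)
          kids <- list(simFromEdge(e, at), simFromEdge(e, at))
        } else {
          rec <- if (nedge > 1L) sample(setdiff(seq_len(nedge), e), 1L) else e
          events[[nEvents]] <<- data.frame(kind = kind, donor_edge = e,
                                           recipient_edge = rec,
                                           position = at)
          kids <- list(simFromEdge(e, at), simFromEdge(rec, 0))
        }
        return(combine(kids, at - pos))
      }
      child <- edge[e, 2L]
      if (child <= ntip) return(leafNode(child, L - pos))
      combine(lapply(childEdges[[as.character(child)]], simFromEdge, pos = 0),
              L - pos)
    }

    root <- ntip + 1L
    rootKids <- lapply(childEdges[[as.character(root)]], simFromEdge, pos = 0)
    geneRoot <- combine(rootKids, 0)

    eventsDf <- if (nEvents > 0L) do.call(rbind, events[seq_len(nEvents)])
      else data.frame(kind = character(), donor_edge = integer(),
                      recipient_edge = integer(), position = numeric())

    counts <- setNames(integer(ntip), species_tree$tip.label)
    if (is.null(geneRoot)) {
      fam <- GeneFamily(family_id, counts)
      return(list(family = fam, events = eventsDf))
    }
    nl <- countLeaves(geneRoot)
    if (nl == 1L) {
      lbl <- geneRoot$label
      counts[leafGenome(lbl)] <- 1L
      seqs <- Biostrings::DNAStringSet(setNames(
        paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
              collapse = ""), lbl))
      fam <- GeneFamily(family_id, counts, members = lbl, alignment = seqs)
      return(list(family = fam, events = eventsDf))
    }
    gtree <- readNewick(paste0(nodeNewick(geneRoot), ";"))
    tab <- table(leafGenome(gtree$tip.label))
    counts[names(tab)] <- as.integer(tab)
    aln <- evolveSequences(gtree, n_sites)
    fam <- GeneFamily(family_id, counts, members = gtree$tip.label,
                      alignment = aln, tree = gtree)
    list(family = fam, events = eventsDf)
  })
}

#' Evolve ungapped sequences along a tree under JC69
#'
#' The root sequence is uniform over \{A,C,G,T\}; each branch applies the
#' Jukes-Cantor transition kernel for its length in expected
#' substitutions/site (per site: retain with probability
#' \eqn{e^{-4b/3}}, otherwise redraw uniformly over the four bases).
#'
#' @param tree [ape::phylo] with branch lengths in substitutions/site.
#' @param n_sites Number of sites.
#' @param model Substitution model; only `"JC69"`.
#' @param seed Optional integer seed.
#' @param root_seq Optional root sequence (character scalar of `n_sites`).
#' @return `Biostrings::DNAStringSet` named by leaf labels.
#' @export
evolveSequences <- function(tree, n_sites = 300L, model = "JC69",
                            seed = NULL, root_seq = NULL) {
  model <- match.arg(model, "JC69")
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L)
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    ntip <- length(tree$tip.label)
    nnode <- max(tree$edge)
    seqs <- matrix(NA_character_, nrow = nnode, ncol = n_sites)
    root <- ntip + 1L
    seqs[root, ] <- if (is.null(root_seq))
      sample(bases, n_sites, replace = TRUE)
    else {
      rs <- strsplit(toupper(root_seq), "")[[1L]]
      if (length(rs) != n_sites) stop("root_seq has wrong length")
      rs
    }
    po <- ape::reorder.phylo(tree, "postorder")
    for (k in rev(seq_len(nrow(po$edge)))) {      # preorder over edges
      p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
      b <- po$edge.length[k]
      s <- seqs[p, ]
      keep <- runif(n_sites) < exp(-4 * b / 3)
      if (!all(keep)) s[!keep] <- sample(bases, sum(!keep), replace = TRUE)
      seqs[ch, ] <- s
    }
    out <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L, paste,
                 collapse = "")
    Biostrings::DNAStringSet(setNames(out, tree$tip.label))
  })
}

# Total JC path divergence giving a target expected identity.
jcTimeForIdentity <- function(identity) {
  if (identity <= 0.25 || identity > 1)
    stop("target identity must be in (0.25, 1]")
  -0.75 * log((identity - 0.25) / 0.75)
}

jcMutate <- function(x, t) {
  keep <- runif(length(x)) < exp(-4 * t / 3)
  x[!keep] <- sample(c("A", "C", "G", "T"), sum(!keep), replace = TRUE)
  x
}

#' Simulate 16S-style sequence sets with planted group structure
#'
#' Group ancestors radiate from a common root so the expected between-group
#' identity matches `inter_identity`; members radiate within each group so
#' the expected within-group identity matches `intra_identity` (JC69
#' expectations). Records are 5'-anchored partial sequences: ungapped
#' lengths are drawn uniformly from `len_range` (dipping below typical
#' length-filter cutoffs) and the remainder of each alignment row is
#' gap-filled, so all records share comparable columns.
#'
#' @param n_groups Number of planted groups.
#' @param seqs_per_group Members per group.
#' @param width Alignment width (sites).
#' @param intra_identity Target mean within-group identity (default 0.98).
#' @param inter_identity Target mean between-group identity (default 0.88).
#' @param len_range Integer range of ungapped record lengths.
#' @param max_offset Maximum random 5' offset (columns).
#' @param seed Optional integer seed.
#' @return List with `sequences` (aligned `DNAStringSet`), `groups`
#'   (`data.frame` `id`, `group`) and `params`.
#' @export
simulate16SGroups <- function(n_groups = 3L, seqs_per_group = 8L,
                              width = 1200L, intra_identity = 0.98,
                              inter_identity = 0.88,
                              len_range = c(650L, width),
                              max_offset = 40L, seed = NULL) {
  if (!(inter_identity < intra_identity && intra_identity < 1))
    stop("infeasible identity targets: need inter < intra < 1")
  stopifnot(n_groups >= 1L, seqs_per_group >= 1L,
            len_range[1L] >= max_offset + 200L, len_range[2L] <= width)
  withSeed(seed, {
    tIntra <- jcTimeForIdentity(intra_identity)
    tInter <- jcTimeForIdentity(inter_identity)
    bw <- tIntra / 2
    bg <- (tInter - tIntra) / 2
    root <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    ids <- character(); grp <- character(); rows <- character()
    for (g in seq_len(n_groups)) {
      anc <- jcMutate(root, bg)
      for (j in seq_len(seqs_per_group)) {
        s <- jcMutate(anc, bw)
        off <- sample.int(max_offset + 1L, 1L) - 1L
        len <- sample(len_range[1L]:len_range[2L], 1L)
        lo <- off + 1L
        hi <- min(off + len, width)
        s[-(lo:hi)] <- "-"
        ids <- c(ids, sprintf("G%d_%d", g, j))
        grp <- c(grp, sprintf("G%d", g))
        rows <- c(rows, paste(s, collapse = ""))
      }
    }
    list(sequences = Biostrings::DNAStringSet(setNames(rows, ids)),
         groups = data.frame(id = ids, group = grp,
                             stringsAsFactors = FALSE),
         params = list(n_groups = n_groups, seqs_per_group = seqs_per_group,
                       width = width, intra_identity = intra_identity,
                       inter_identity = inter_identity))
  })
}

#' Simulate mapped-read counts over genomes
#'
#' Per-sample multinomial draw with mapping probability proportional to
#' `true_fractions * genome_lengths` (reads proportional to genome length);
#' a `mapped_fraction < 1` leaves the remaining reads unmapped.
#'
#' @param true_fractions Named per-genome abundance fractions (sum to 1).
#' @param genome_lengths Named genome lengths in bp (> 0).
#' @param total_reads Per-sample total read counts (one sample per entry).
#' @param mapped_fraction Fraction of reads mapping to any genome.
#' @param seed Optional integer seed.
#' @return An [AbundanceTable-class].
#' @export
simulateReadCounts <- function(true_fractions, genome_lengths, total_reads,
                               mapped_fraction = 1, seed = NULL) {
  if (abs(sum(true_fractions) - 1) > 1e-8)
    stop("true_fractions must sum to 1")
  if (any(genome_lengths <= 0)) stop("genome lengths must be positive")
  stopifnot(mapped_fraction > 0, mapped_fraction <= 1)
  g <- names(true_fractions)
  if (is.null(g)) stop("true_fractions must be named by genome")
  withSeed(seed, {
    p <- true_fractions * genome_lengths[g]
    p <- p / sum(p) * mapped_fraction
    probs <- c(p, unmapped = 1 - mapped_fraction)
    counts <- vapply(total_reads, function(n)
      rmultinom(1L, n, probs)[seq_along(g), 1L],
      numeric(length(g)))
    counts <- matrix(counts, nrow = length(g),
                     dimnames = list(g, paste0("S", seq_along(total_reads))))
    AbundanceTable(counts, genome_lengths[g], total_reads)
  })
}

#' Simulate a genome x gene-symbol annotation matrix
#'
#' Each genome receives every signature gene of its group; with
#' `dropout = TRUE` each gene is independently retained with probability
#' `completeness / 100`, emulating incomplete MAG recovery.
#'
#' @param genomes `data.frame` with columns `id`, `group`, `completeness`.
#' @param signatures Named list: group -> character vector of gene symbols.
#' @param dropout Apply completeness-driven dropout?
#' @param seed Optional integer seed.
#' @return Integer matrix (genomes x gene symbols), a presence/copy matrix.
#' @export
simulateAnnotationTable <- function(genomes, signatures, dropout = FALSE,
                                    seed = NULL) {
  stopifnot(all(c("id", "group", "completeness") %in% colnames(genomes)))
  unknown <- setdiff(unique(genomes$group), names(signatures))
  if (length(unknown))
    stop("no signature for group(s): ", paste(unknown, collapse = ", "))
  genes <- sort(unique(unlist(signatures, use.names = FALSE)))
  withSeed(seed, {
    m <- matrix(0L, nrow = nrow(genomes), ncol = length(genes),
                dimnames = list(genomes$id, genes))
    for (i in seq_len(nrow(genomes))) {
      sig <- signatures[[genomes$group[i]]]
      present <- if (dropout)
        sig[runif(length(sig)) < genomes$completeness[i] / 100]
      else sig
      m[i, present] <- 1L
    }
    m
  })
}

#' Simulate binary presence/absence profiles down a species tree
#'
#' Evolves a two-state (absent/present) character under the continuous-time
#' chain with gain rate `gain` (0 to 1) and loss rate `loss` (1 to 0); the
#' root state is drawn from `root_prior` (default: the stationary
#' probability of presence). Realised endpoint transitions per branch are
#' recorded as the planted truth for event-recovery tests.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param gain,loss Transition rates per branch-length unit.
#' @param n_families Number of independent characters.
#' @param root_prior Probability the root is in state 1.
#' @param seed Optional integer seed.
#' @return List: `profiles` (n_families x leaves 0/1 matrix), `gains` and
#'   `losses` (n_families x edges endpoint-transition indicators, columns
#'   ordered as `tree$edge`).
#' @export
simulateBinaryProfiles <- function(tree, gain, loss, n_families = 100L,
                                   root_prior = gain / (gain + loss),
                                   seed = NULL) {
  stopifnot(gain >= 0, loss >= 0, gain + loss > 0)
  withSeed(seed, {
    ntip <- length(tree$tip.label)
    po <- ape::reorder.phylo(tree, "postorder")
    nedge <- nrow(po$edge)
    profiles <- matrix(0L, n_families, ntip,
                       dimnames = list(NULL, tree$tip.label))
    gains <- matrix(0L, n_families, nedge)
    losses <- matrix(0L, n_families, nedge)
    for (f in seq_len(n_families)) {
      st <- integer(max(tree$edge))
      st[ntip + 1L] <- as.integer(runif(1L) < root_prior)
      for (k in rev(seq_len(nedge))) {            # preorder over edges
        p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
        P <- mkTransition(gain, loss, po$edge.length[k])
        st[ch] <- as.integer(runif(1L) < P[st[p] + 1L, 2L])
        if (st[p] == 0L && st[ch] == 1L) gains[f, k] <- 1L
        if (st[p] == 1L && st[ch] == 0L) losses[f, k] <- 1L
      }
      profiles[f, ] <- st[seq_len(ntip)]
    }
    # report event columns in tree$edge order
    eo <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
                paste(po$edge[, 1L], po$edge[, 2L]))
    list(profiles = profiles, gains = gains[, eo, drop = FALSE],
         losses = losses[, eo, drop = FALSE])
  })
}
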