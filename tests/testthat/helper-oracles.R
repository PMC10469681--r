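# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: splits come from phangorn, parsimony/likelihood from
# exhaustive enumeration, ranks from an explicit definition.

# All bipartition sides of the unrooted tree (both orientations), via
# phangorn's split machinery.
oracleSides <- function(tree) {
  sp <- phangorn::as.splits(ape::unroot(tree))
  labs <- attr(sp, "labels")
  sides <- lapply(seq_along(sp), function(i) sort(labs[sp[[i]]]))
  comp <- lapply(sides, function(s) sort(setdiff(labs, s)))
  unique(c(sides, comp, list(sort(labs))))
}

oracleMonophyletic <- function(tree, focal) {
  focal <- sort(focal)
  n <- length(tree$tip.label)
  if (length(focal) %in% c(1L, n)) return(TRUE)
  any(vapply(oracleSides(tree), function(s) identical(s, focal),
             logical(1L)))
}

oracleMinimalSide <- function(tree, focal) {
  focal <- sort(focal)
  sides <- Filter(function(s) all(focal %in% s) && length(s) > 0,
                  oracleSides(tree))
  sizes <- lengths(sides)
  cand <- sides[sizes == min(sizes)]
  keys <- vapply(cand, paste, character(1L), collapse = "\r")
  cand[[order(keys)[1L]]]
}

# Exhaustive small-parsimony minimum over all internal 0/1 labelings.
oracleFitch <- function(tree, profile) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internals <- (ntip + 1L):nnode
  states <- integer(nnode)
  states[seq_len(ntip)] <- profile[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^length(internals) - 1L)) {
    states[internals] <- bitwAnd(bitwShiftR(mask,
                                            seq_along(internals) - 1L), 1L)
    ch <- sum(states[tree$edge[, 1L]] != states[tree$edge[, 2L]])
    best <- min(best, ch)
  }
  best
}

# Exhaustive two-state likelihood: sum over all internal assignments of
# prior x product of analytic transition probabilities.
oracleMkLoglik <- function(tree, profile, gain, loss, root_prior) {
  trans <- function(t) {
    r <- gain + loss
    if (r == 0 || t == 0) return(diag(2))
    e <- exp(-r * t)
    matrix(c((loss + gain * e) / r, gain * (1 - e) / r,
             loss * (1 - e) / r, (gain + loss * e) / r), 2L, byrow = TRUE)
  }
  P <- lapply(tree$edge.length, trans)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  internals <- (ntip + 1L):nnode
  states <- integer(nnode)
  states[seq_len(ntip)] <- profile[tree$tip.label]
  prior <- c(1 - root_prior, root_prior)
  lik <- 0
  for (mask in 0:(2^length(internals) - 1L)) {
    states[internals] <- bitwAnd(bitwShiftR(mask,
                                            seq_along(internals) - 1L), 1L)
    pr <- prior[states[ntip + 1L] + 1L]
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * P[[k]][states[tree$edge[k, 1L]] + 1L,
                        states[tree$edge[k, 2L]] + 1L]
    lik <- lik + pr
  }
  log(lik)
}

# Explicit average ranks (definition, not rank()).
oracleAvgRank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}

oracleSpearman <- function(x, y) {
  rx <- oracleAvgRank(x); ry <- oracleAvgRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random tree with nonzero branch lengths (additive-distance source).
randomTree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  tr
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Closed-form expected event count for a pure-duplication family: lineages
# multiply as e^(rate * l) along each branch, starting from one at the root.
expectedDupCount <- function(tree, rate) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  m <- numeric(max(tree$edge))
  m[ntip + 1L] <- 1
  total <- 0
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    l <- po$edge.length[k]
    total <- total + m[p] * (exp(rate * l) - 1)
    m[ch] <- m[p] * exp(rate * l)
  }
  total
}
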