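# Simplified ancestral gene-content reconstruction on a fixed species tree:
# Fitch small parsimony and a two-state continuous-time Markov model
# (gain/loss) with Felsenstein pruning. Presence/absence histories only:
# transfers are not distinguishable from independent gains here.

#' Two-state gain/loss model
#'
#' @param gain Rate of 0 -> 1 (gain) per branch-length unit.
#' @param loss Rate of 1 -> 0 (loss) per branch-length unit.
#' @param root_prior Probability of state 1 at the root; defaults to the
#'   stationary probability `gain / (gain + loss)`.
#' @return A named list of class `"mk_model"`.
#' @export
mkModel <- function(gain, loss, root_prior = gain / (gain + loss)) {
  stopifnot(gain >= 0, loss >= 0, gain + loss > 0,
            root_prior >= 0, root_prior <= 1)
  structure(list(gain = gain, loss = loss, root_prior = root_prior),
            class = "mk_model")
}

# Analytic 2-state transition matrix over time t (rows: from 0/1).
mkTransition <- function(gain, loss, t) {
  r <- gain + loss
  if (r == 0 || t == 0) return(diag(2))
  e <- exp(-r * t)
  matrix(c((loss + gain * e) / r, gain * (1 - e) / r,
           loss * (1 - e) / r, (gain + loss * e) / r),
         nrow = 2L, byrow = TRUE)
}

checkProfile <- function(tree, profile) {
  ntip <- length(tree$tip.label)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  profile <- profile[tree$tip.label]
  if (anyNA(profile) || is.null(names(profile)))
    stop("every leaf needs a 0/1 state; unlabeled: ",
         paste(tree$tip.label[is.na(profile)], collapse = ", "))
  if (!all(profile %in% c(0L, 1L))) stop("states must be 0/1")
  as.integer(profile)
}

#' Fitch small parsimony for a binary presence/absence profile
#'
#' Bottom-up Fitch state sets, counting one change per empty intersection;
#' the top-down refinement picks the parent's state when available and
#' prefers state 0 (absent) at ambiguous nodes, yielding one optimal
#' labeling.
#'
#' @param tree Rooted binary [ape::phylo].
#' @param profile Named 0/1 vector over the tree's leaves.
#' @return List with `changes` (the parsimony minimum) and `labeling`
#'   (named 0/1 vector over all nodes; internal nodes named `"node<i>"`).
#' @examples
#' tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' fitchMinChanges(tr, c(A = 1, B = 1, C = 0, D = 0))$changes
#' @export
fitchMinChanges <- function(tree, profile) {
  profile <- checkProfile(tree, profile)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  sets <- integer(nnode)                     # bitmask: 1 = {0}, 2 = {1}
  sets[seq_len(ntip)] <- ifelse(profile == 1L, 2L, 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  # postorder guarantees a child's set is final when its edge is reached;
  # fold children into the parent one edge at a time
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    if (sets[p] == 0L) {
      sets[p] <- sets[ch]
    } else {
      meet <- bitwAnd(sets[p], sets[ch])
      if (meet == 0L) {
        sets[p] <- bitwOr(sets[p], sets[ch])
        changes <- changes + 1L
      } else sets[p] <- meet
    }
  }
  lab <- integer(nnode)
  root <- ntip + 1L
  lab[root] <- if (bitwAnd(sets[root], 1L) > 0L) 0L else 1L
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    pbit <- bitwShiftL(1L, lab[p])
    lab[ch] <- if (bitwAnd(sets[ch], pbit) > 0L) lab[p]
    else if (bitwAnd(sets[ch], 1L) > 0L) 0L else 1L
  }
  names(lab) <- c(tree$tip.label,
                  paste0("node", (ntip + 1L):nnode))
  list(changes = changes, labeling = lab)
}

# Up-pass partial likelihoods L[v, s] = P(leaf data below v | state s at v).
mkUpPass <- function(tree, profile, model) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  L <- matrix(1, nnode, 2L)
  L[cbind(seq_len(ntip), 2L - profile)] <- 0   # leaf state known
  po <- ape::reorder.phylo(tree, "postorder")
  P <- lapply(seq_len(nrow(po$edge)), function(k)
    mkTransition(model$gain, model$loss, po$edge.length[k]))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    L[p, ] <- L[p, ] * as.vector(P[[k]] %*% L[ch, ])
  }
  list(L = L, po = po, P = P)
}

#' Marginal ancestral presence probabilities under the two-state model
#'
#' Felsenstein pruning under the continuous-time gain/loss chain, followed
#' by a down-pass giving the marginal posterior probability of presence at
#' every node, and the log-likelihood of the leaf data. Zero-length
#' branches use the identity transition matrix.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param profile Named 0/1 vector over the leaves.
#' @param model An [mkModel()].
#' @return List with `posterior` (named vector, P(state = 1) per node,
#'   leaves included), `loglik`, and `joint` (per-edge 2x2 joint posterior
#'   of parent/child states, in `tree$edge` order, used by
#'   [branchEvents()]).
#' @export
mkAncestral <- function(tree, profile, model) {
  stopifnot(inherits(model, "mk_model"))
  profile <- checkProfile(tree, profile)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  up <- mkUpPass(tree, profile, model)
  L <- up$L; po <- up$po; P <- up$P
  root <- ntip + 1L
  prior <- c(1 - model$root_prior, model$root_prior)
  lik <- sum(prior * L[root, ])
  if (lik <= 0) stop("data have zero likelihood under the model")
  # Down-pass: G[v, s] = P(data outside subtree of v, state s at v)
  G <- matrix(0, nnode, 2L)
  G[root, ] <- prior
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sibs <- setdiff(kids[[as.character(p)]], k)
    out <- G[p, ]
    for (s in sibs) out <- out * as.vector(P[[s]] %*% L[po$edge[s, 2L], ])
    G[ch, ] <- as.vector(t(P[[k]]) %*% out)
  }
  post <- (G * L)
  post <- post[, 2L] / rowSums(post)
  names(post) <- c(tree$tip.label, paste0("node", (ntip + 1L):nnode))
  joint <- lapply(seq_len(nrow(po$edge)), function(k) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sibs <- setdiff(kids[[as.character(p)]], k)
    out <- G[p, ]
    for (s in sibs) out <- out * as.vector(P[[s]] %*% L[po$edge[s, 2L], ])
    J <- outer(out, L[ch, ]) * P[[k]]
    J / sum(J)
  })
  eo <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
              paste(po$edge[, 1L], po$edge[, 2L]))
  list(posterior = post, loglik = log(lik), joint = joint[eo])
}

#' Per-branch gain and loss events
#'
#' Parsimony mode counts 0 -> 1 (gain) and 1 -> 0 (loss) endpoint
#' transitions along each branch of a Fitch-optimal labeling; their total
#' equals the Fitch minimum. Expected mode sums the posterior endpoint
#' transition probabilities from [mkAncestral()].
#'
#' @param tree Rooted [ape::phylo].
#' @param fit Result of [fitchMinChanges()] (parsimony mode) or
#'   [mkAncestral()] (expected mode).
#' @param mode `"parsimony"` or `"expected"`.
#' @return `data.frame` with one row per edge of `tree$edge`: `parent`,
#'   `child`, `gain`, `loss`.
#' @export
branchEvents <- function(tree, fit, mode = c("parsimony", "expected")) {
  mode <- match.arg(mode)
  edge <- tree$edge
  if (mode == "parsimony") {
    lab <- fit$labeling
    ps <- lab[edge[, 1L]]
    cs <- lab[edge[, 2L]]
    gain <- as.numeric(ps == 0L & cs == 1L)
    loss <- as.numeric(ps == 1L & cs == 0L)
  } else {
    gain <- vapply(fit$joint, function(J) J[1L, 2L], numeric(1L))
    loss <- vapply(fit$joint, function(J) J[2L, 1L], numeric(1L))
  }
  data.frame(parent = edge[, 1L], child = edge[, 2L], gain = gain,
             loss = loss)
}

#' Estimate gain/loss rates by maximum likelihood
#'
#' Optimises the pruning log-likelihood summed over binary profiles on the
#' log-rate scale (Nelder-Mead, relative tolerance 1e-6); the root prior
#' tracks the stationary distribution of the candidate rates.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param profiles Matrix of 0/1 profiles (families x leaves, columns
#'   named by leaf).
#' @param init Starting `c(gain, loss)`.
#' @return List with `model` (an [mkModel()]) and `loglik`.
#' @export
estimateMkRates <- function(tree, profiles, init = c(0.5, 0.5)) {
  nll <- function(par) {
    g <- exp(par[1L]); l <- exp(par[2L])
    m <- mkModel(g, l)
    -sum(apply(profiles, 1L, function(pr)
      mkAncestral(tree, pr, m)$loglik))
  }
  fit <- optim(log(init), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-6))
  model <- mkModel(exp(fit$par[1L]), exp(fit$par[2L]))
  list(model = model, loglik = -fit$value)
}
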