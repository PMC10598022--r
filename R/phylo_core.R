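# Tree algebra shared by every analysis: MRCA/paths, times, phylogenetic
# covariance, Brownian simulation, and binary-trait permulation nulls.
# Trees are ape `phylo` objects; nodes are addressed by tip label, by the
# canonical `nd<k>` internal label, or by ape's integer index.

#' Run code with a temporary RNG seed, restoring global RNG state
#' @param seed Integer seed (or `NULL` to leave the RNG alone).
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  code
}

#' Resolve a node reference to ape's integer index
#' @param tree A `phylo`.
#' @param node Tip label, internal `node.label`, or integer index.
#' @return Integer node index.
#' @export
node_index <- function(tree, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (any(node < 1L | node > ape::Ntip(tree) + tree$Nnode)) {
      stop("node index out of range")
    }
    return(node)
  }
  n <- ape::Ntip(tree)
  idx <- match(node, tree$tip.label)
  if (!is.null(tree$node.label)) {
    ni <- match(node, tree$node.label)
    idx[is.na(idx)] <- n + ni[is.na(idx)]
  }
  if (anyNA(idx)) stop("unknown node(s): ", paste(node[is.na(idx)], collapse = ", "))
  idx
}

# parent[i] = ape index of i's parent (0 for root)
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

#' Node depths (distance from the root)
#' @param tree A `phylo` with branch lengths.
#' @return Numeric vector over all nodes (tips first, ape order).
#' @export
node_depths <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  d <- numeric(ntot)
  pr <- ape::reorder.phylo(tree, "postorder")
  # walk edges root-ward order reversed = preorder
  for (i in rev(seq_len(nrow(pr$edge)))) {
    d[pr$edge[i, 2L]] <- d[pr$edge[i, 1L]] + pr$edge.length[i]
  }
  d
}

#' Most recent common ancestor of two distinct tips
#' @param tree A `phylo`.
#' @param tip_a,tip_b Tip labels (must differ).
#' @return Integer node index of the MRCA.
#' @export
mrca_node <- function(tree, tip_a, tip_b) {
  if (identical(tip_a, tip_b)) stop("pair must be two distinct tips")
  i <- node_index(tree, tip_a)
  j <- node_index(tree, tip_b)
  if (i > ape::Ntip(tree) || j > ape::Ntip(tree)) stop("arguments must be tips")
  p <- parent_vector(tree)
  anc_i <- i
  while (p[anc_i[length(anc_i)]] != 0L) anc_i <- c(anc_i, p[anc_i[length(anc_i)]])
  node <- j
  while (!(node %in% anc_i)) node <- p[node]
  node
}

tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  dep <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(dep)
  if (max(dep) - min(dep) > rel_tol * h) {
    stop("tree is not ultrametric (tip depth spread ",
         signif(max(dep) - min(dep), 3), " exceeds tolerance)")
  }
  h
}

#' Divergence time of a pair of tips on an ultrametric tree
#'
#' Depth of the pair's MRCA below the present; symmetric in its arguments.
#'
#' @param tree Ultrametric `phylo` (relative tolerance `1e-6` of height).
#' @param tip_a,tip_b Tip labels.
#' @return Divergence time in the tree's branch-length units.
#' @export
divergence_time <- function(tree, tip_a, tip_b) {
  h <- assert_ultrametric(tree)
  h - node_depths(tree)[mrca_node(tree, tip_a, tip_b)]
}

#' Ordered branches from an ancestor (exclusive) to a tip (inclusive)
#'
#' @param tree A `phylo`.
#' @param ancestor Node reference ancestral to `tip`.
#' @param tip Tip label.
#' @return Integer vector of edge indices into `tree$edge`, root-ward first.
#' @export
path_branches <- function(tree, ancestor, tip) {
  anc <- node_index(tree, ancestor)
  node <- node_index(tree, tip)
  p <- parent_vector(tree)
  edges <- integer(0)
  while (node != anc) {
    if (p[node] == 0L) stop("'", ancestor, "' is not ancestral to '", tip, "'")
    edges <- c(which(tree$edge[, 2L] == node), edges)
    node <- p[node]
  }
  edges
}

#' Phylogenetic covariance of a set of nodes
#'
#' Entry (i, j) is the shared root-path length of nodes i and j (the depth
#' of their most recent common ancestor); the diagonal holds node depths.
#'
#' @param tree A `phylo` with branch lengths.
#' @param node_set Vector of node references (tips and/or internal nodes).
#' @return Symmetric positive semidefinite matrix with `node_set` dimnames.
#' @export
phylo_covariance <- function(tree, node_set) {
  if (length(node_set) == 0L) stop("empty node_set")
  idx <- node_index(tree, node_set)
  p <- parent_vector(tree)
  dep <- node_depths(tree)
  # root-path ancestor sets (including self)
  paths <- lapply(idx, function(i) {
    a <- i
    while (p[a[length(a)]] != 0L) a <- c(a, p[a[length(a)]])
    a
  })
  m <- length(idx)
  C <- matrix(0, m, m, dimnames = list(as.character(node_set), as.character(node_set)))
  for (i in seq_len(m)) {
    C[i, i] <- dep[idx[i]]
    if (i < m) for (j in seq((i + 1L), m)) {
      common <- intersect(paths[[i]], paths[[j]])
      # MRCA = deepest common ancestor
      C[i, j] <- C[j, i] <- max(dep[common])
    }
  }
  C
}

#' Simulate Brownian motion tip values
#'
#' Draws tip values from a multivariate normal with covariance
#' `sigma2 * phylo_covariance(tree, tips)`.
#'
#' @param tree A `phylo`.
#' @param sigma2 Brownian rate (> 0).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return Named numeric vector over tips.
#' @export
simulate_bm <- function(tree, sigma2 = 1, seed = NULL) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  C <- phylo_covariance(tree, tree$tip.label)
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(C))
  with_seed(seed, {
    z <- stats::rnorm(nrow(C))
    stats::setNames(sqrt(sigma2) * as.numeric(L %*% z), tree$tip.label)
  })
}

#' Count maximal foreground-only clades ("origins") of a tip set
#' @param tree A `phylo`.
#' @param foreground_tips Character vector of foreground tip labels.
#' @return Integer count of maximal clades whose tips are all foreground.
#' @export
count_foreground_clades <- function(tree, foreground_tips) {
  n <- ape::Ntip(tree)
  fg <- tree$tip.label %in% foreground_tips
  if (!any(fg)) return(0L)
  ntot <- n + tree$Nnode
  allfg <- logical(ntot)
  allfg[seq_len(n)] <- fg
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    allfg[node] <- all(allfg[kids[[as.character(node)]]])
  }
  p <- parent_vector(tree)
  sum(vapply(seq_len(ntot), function(i) {
    allfg[i] && (p[i] == 0L || !allfg[p[i]])
  }, logical(1)))
}

#' Permulate a binary foreground tip set
#'
#' Phylogenetic permutation ("permulation") of a binary trait: simulate a
#' Brownian history on the tree and assign foreground status to the tips
#' with the k largest simulated values, k being the observed foreground
#' count.  With `match_origins = TRUE`, draws are rejected until the
#' permuted set has exactly as many maximal foreground-only clades as the
#' observed set.
#'
#' @param tree A `phylo`.
#' @param observed_foreground_tips Character vector (1 <= k < n tips).
#' @param seed Optional integer seed.
#' @param match_origins Logical; constrain the origin count (default FALSE).
#' @param max_tries Rejection-sampling cap (default 10000).
#' @return Character vector of permuted foreground tip labels.
#' @export
permulate_binary <- function(tree, observed_foreground_tips, seed = NULL,
                             match_origins = FALSE, max_tries = 10000) {
  k <- length(observed_foreground_tips)
  n <- ape::Ntip(tree)
  if (k < 1L || k >= n) stop("need 1 <= |foreground| < n_tips")
  C <- phylo_covariance(tree, tree$tip.label)
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  target <- if (match_origins) {
    count_foreground_clades(tree, observed_foreground_tips)
  } else NA_integer_
  with_seed(seed, {
    achieved <- integer(0)
    for (try in seq_len(max_tries)) {
      y <- as.numeric(L %*% stats::rnorm(n))
      fg <- tree$tip.label[order(y, decreasing = TRUE)[seq_len(k)]]
      if (!match_origins) return(fg)
      got <- count_foreground_clades(tree, fg)
      if (got == target) return(fg)
      achieved <- c(achieved, got)
    }
    stop("max_tries (", max_tries, ") exhausted; target origins ", target,
         ", achieved counts ranged ", min(achieved), "-", max(achieved))
  })
}

#' All unordered distinct pairs of tips
#'
#' @param tips Character vector of >= 2 labels.
#' @return Data frame with columns `a`, `b` in lexicographic order;
#'   `choose(n, 2)` rows.
#' @export
enumerate_pairs <- function(tips) {
  if (length(tips) < 2L) stop("need at least 2 tips")
  tips <- sort(unique(as.character(tips)))
  if (length(tips) < 2L) stop("need at least 2 distinct tips")
  idx <- utils::combn(length(tips), 2L)
  data.frame(a = tips[idx[1L, ]], b = tips[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Fitch parsimony reconstruction of a binary trait
#'
#' Minimum-change reconstruction with deterministic tie-breaking: an
#' ambiguous root is resolved to state 0 (absence); an ambiguous non-root
#' node inherits its parent's state.  Origins are 0 -> 1 transitions
#' (a root reconstructed in state 1 counts as one origin).
#'
#' @param tree A `phylo`.
#' @param trait Named 0/1 vector covering all tips.
#' @return List with `states` (0/1 over all nodes, ape order), `origins`
#'   (count of gains) and `changes` (total state changes on edges).
#' @export
fitch_binary_trait <- function(tree, trait) {
  n <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(trait))) stop("trait must cover all tips")
  x <- trait[tree$tip.label]
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  ntot <- n + tree$Nnode
  # state sets encoded as 1 = {0}, 2 = {1}, 3 = {0,1}
  setcode <- integer(ntot)
  setcode[seq_len(n)] <- ifelse(x == 1, 2L, 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    cs <- setcode[kids[[as.character(node)]]]
    inter <- Reduce(bitwAnd, cs)
    setcode[node] <- if (inter > 0L) inter else Reduce(bitwOr, cs)
  }
  p <- parent_vector(tree)
  states <- integer(ntot)
  resolve <- function(node, parent_state) {
    sc <- setcode[node]
    if (sc == 3L) parent_state else sc - 1L
  }
  root <- n + 1L
  states[root] <- if (setcode[root] == 3L) 0L else setcode[root] - 1L
  for (i in rev(seq_len(nrow(po$edge)))) {   # preorder
    child <- po$edge[i, 2L]
    states[child] <- resolve(child, states[po$edge[i, 1L]])
  }
  edge_changes <- states[tree$edge[, 1L]] != states[tree$edge[, 2L]]
  gains <- states[tree$edge[, 1L]] == 0L & states[tree$edge[, 2L]] == 1L
  list(states = states,
       origins = sum(gains) + (states[root] == 1L),
       changes = sum(edge_changes))
}
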