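# Shared fixtures and independent oracles, built in code at test time.

tree3 <- function() canonical_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
tree4 <- function() {
  canonical_tree(ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);"))
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  canonical_tree(tr)
}

tree_height_of <- function(tr) max(ape::node.depth.edgelength(tr))

star_tree <- function(n) {
  txt <- paste0("(", paste(sprintf("s%02d:1", seq_len(n)), collapse = ","), ");")
  canonical_tree(ape::read.tree(text = txt))
}

# write a minimal PSMC output file with one or more iteration rounds
write_psmc_fixture <- function(path, theta0 = 0.004, t_k = (0:9) / 10,
                               lambda_k = rep(1, 10), rounds = 2) {
  lines <- character(0)
  for (r in seq_len(rounds) - 1L) {
    lines <- c(lines,
               sprintf("RD\t%d", r),
               sprintf("TR\t%g\t%g", theta0, theta0 / 5),
               sprintf("RS\t%d\t%g\t%g\t0\t0\t0", seq_along(t_k) - 1L,
                       t_k, lambda_k),
               "//")
  }
  writeLines(lines, path)
  path
}

# exhaustive-enumeration likelihood of one alignment column: sum over all
# internal labelings of prod(edge transition probs) * root prior
brute_force_likelihood <- function(tree, column, model = equal_rates_model()) {
  n <- ape::Ntip(tree)
  aa <- model$states
  tipstate <- match(toupper(column[tree$tip.label]), aa)
  internal <- (n + 1L):(n + tree$Nnode)
  labelings <- as.matrix(expand.grid(rep(list(seq_len(model$k)), tree$Nnode)))
  Pe <- lapply(tree$edge.length, function(t) transition_matrix(model, t))
  state_of <- function(lab, node) {
    if (node <= n) tipstate[node] else lab[node - n]
  }
  total <- 0
  for (r in seq_len(nrow(labelings))) {
    lab <- labelings[r, ]
    pr <- 1 / model$k
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pe[[e]][state_of(lab, tree$edge[e, 1L]),
                         state_of(lab, tree$edge[e, 2L])]
    }
    total <- total + pr
  }
  total
}

# exhaustive marginal posterior for one internal node, one column
brute_force_posterior <- function(tree, column, node_label,
                                  model = equal_rates_model()) {
  n <- ape::Ntip(tree)
  node <- node_index(tree, node_label)
  aa <- model$states
  tipstate <- match(toupper(column[tree$tip.label]), aa)
  labelings <- as.matrix(expand.grid(rep(list(seq_len(model$k)), tree$Nnode)))
  Pe <- lapply(tree$edge.length, function(t) transition_matrix(model, t))
  state_of <- function(lab, nd) if (nd <= n) tipstate[nd] else lab[nd - n]
  mass <- numeric(model$k)
  for (r in seq_len(nrow(labelings))) {
    lab <- labelings[r, ]
    pr <- 1 / model$k
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pe[[e]][state_of(lab, tree$edge[e, 1L]),
                         state_of(lab, tree$edge[e, 2L])]
    }
    mass[lab[node - n]] <- mass[lab[node - n]] + pr
  }
  stats::setNames(mass / sum(mass), aa)
}

# naive per-site three-way comparison of tip states against the MRCA state
naive_pair_counts <- function(states, alignment, tree, tip_a, tip_b) {
  aa <- amino_acids()
  lab <- tree$node.label[mrca_node(tree, tip_a, tip_b) - ape::Ntip(tree)]
  C <- D <- 0L
  for (s in seq_len(ncol(alignment))) {
    m <- states$states[lab, s]
    sa <- alignment[tip_a, s]
    sb <- alignment[tip_b, s]
    if (!(m %in% aa) || !(sa %in% aa) || !(sb %in% aa)) next
    if (sa == sb && sa != m) C <- C + 1L
    if (sa != sb && sa != m && sb != m) D <- D + 1L
  }
  c(C = C, D = D)
}

# exhaustive minimum substitution count over internal labelings drawn from
# the states observed at the tips (an optimal labeling uses tip states)
brute_force_parsimony <- function(tree, column) {
  n <- ape::Ntip(tree)
  obs <- unique(column[tree$tip.label])
  labelings <- as.matrix(expand.grid(rep(list(obs), tree$Nnode)))
  state_of <- function(lab, nd) {
    if (nd <= n) column[tree$tip.label][nd] else lab[nd - n]
  }
  best <- Inf
  for (r in seq_len(nrow(labelings))) {
    lab <- labelings[r, ]
    ch <- sum(vapply(seq_len(nrow(tree$edge)), function(e) {
      state_of(lab, tree$edge[e, 1L]) != state_of(lab, tree$edge[e, 2L])
    }, logical(1)))
    best <- min(best, ch)
  }
  best
}
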