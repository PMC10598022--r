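# Ancestral amino-acid reconstruction (pruning under an equal-rates
# 20-state model, or Fitch parsimony) and convergent/divergent substitution
# counting for lineage pairs.  "Lineage" follows path semantics: a tip's
# lineage is the whole MRCA-to-tip path, so counting compares observed tip
# states against the reconstructed MRCA state.

#' Equal-rates 20-state amino-acid substitution model
#'
#' All exchangeabilities equal, uniform stationary frequencies, branch
#' lengths in expected substitutions per site (unit-rate normalization),
#' giving \eqn{P_{ii}(t) = 1/20 + (19/20) e^{-(20/19) t}}.
#'
#' @return An object of class `aa_model`.
#' @export
equal_rates_model <- function() {
  structure(list(states = amino_acids(), k = 20L), class = "aa_model")
}

#' Transition probability matrix of the equal-rates model
#' @param model An `aa_model`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @return 20 x 20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  k <- model$k
  e <- exp(-(k / (k - 1)) * t)
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k - 1 / k * e
  P <- matrix(p_diff, k, k, dimnames = list(model$states, model$states))
  diag(P) <- p_same
  P
}

# tip partial-likelihood matrix (k x S): indicator columns, all-ones for
# gap/unknown symbols
tip_partials <- function(model, seq_chars) {
  k <- model$k
  S <- length(seq_chars)
  m <- matrix(0, k, S)
  hit <- match(seq_chars, model$states)
  known <- !is.na(hit)
  m[cbind(hit[known], which(known))] <- 1
  m[, !known] <- 1
  m
}

# Pruning pass over all sites at once.  Returns per-node partial matrices
# (k x S, rescaled per site) and log-scalers, plus total log-likelihoods.
prune_alignment <- function(tree, aln, model) {
  if (!setequal(rownames(aln), tree$tip.label)) {
    stop("alignment labels do not match tree tips")
  }
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  S <- ncol(aln)
  po <- ape::reorder.phylo(tree, "postorder")
  partials <- vector("list", ntot)
  logscale <- matrix(0, ntot, S)
  for (i in seq_len(n)) partials[[i]] <- tip_partials(model, aln[tree$tip.label[i], ])
  Pmats <- lapply(po$edge.length, function(t) transition_matrix(model, t))
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    acc <- matrix(1, model$k, S)
    sc <- numeric(S)
    for (ei in kids[[as.character(node)]]) {
      child <- po$edge[ei, 2L]
      acc <- acc * (Pmats[[ei]] %*% partials[[child]])
      sc <- sc + logscale[child, ]
    }
    mx <- apply(acc, 2L, max)
    mx[mx == 0] <- 1
    partials[[node]] <- sweep(acc, 2L, mx, "/")
    logscale[node, ] <- sc + log(mx)
  }
  root <- n + 1L
  site_ll <- log(colSums(partials[[root]] / model$k)) + logscale[root, ]
  list(partials = partials, logscale = logscale, site_ll = site_ll,
       po = po, Pmats = Pmats)
}

#' Log-likelihood of one alignment column under the pruning algorithm
#'
#' Marginalizes internal states by Felsenstein pruning; gap/unknown tip
#' symbols contribute uninformative (all-ones) partials.
#'
#' @param tree A `phylo` with branch lengths in expected substitutions.
#' @param alignment_column Named character vector of tip states.
#' @param model An `aa_model` (default [equal_rates_model()]).
#' @return Log-probability of the tip states.
#' @export
site_log_likelihood <- function(tree, alignment_column,
                                model = equal_rates_model()) {
  col <- toupper(alignment_column[tree$tip.label])
  if (anyNA(col)) stop("column must be named by tree tips")
  if (sum(col %in% model$states) < 1L) stop("all-gap column")
  aln <- matrix(col, ncol = 1, dimnames = list(tree$tip.label, NULL))
  prune_alignment(tree, aln, model)$site_ll
}

#' Marginal ancestral amino-acid states
#'
#' Computes, for every internal node and site, the marginal posterior over
#' the 20 amino acids from upward (pruning) and downward partials; the
#' stored state is the argmax, ties broken alphabetically.
#'
#' @param tree A `phylo` with canonical node labels (see [canonical_tree()]).
#' @param alignment Character matrix from [read_fasta()].
#' @param model An `aa_model`.
#' @return An `ancestral_states` object: list with `states` and `posterior`
#'   matrices (internal nodes x sites, rownames = node labels) and
#'   `method = "marginal-ML"`.
#' @export
marginal_ancestral_states <- function(tree, alignment,
                                      model = equal_rates_model()) {
  if (is.null(tree$node.label)) tree <- canonical_tree(tree)
  up <- prune_alignment(tree, alignment, model)
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  S <- ncol(alignment)
  k <- model$k
  po <- up$po
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  # downward ("outside") partials G: G_root = stationary frequencies
  G <- vector("list", ntot)
  root <- n + 1L
  G[[root]] <- matrix(1 / k, k, S)
  for (i in rev(seq_len(nrow(po$edge)))) {  # preorder
    parent <- po$edge[i, 1L]; child <- po$edge[i, 2L]
    sib <- matrix(1, k, S)
    for (ei in kids[[as.character(parent)]]) {
      if (ei == i) next
      sib <- sib * (up$Pmats[[ei]] %*% up$partials[[po$edge[ei, 2L]]])
    }
    gc <- t(up$Pmats[[i]]) %*% (G[[parent]] * sib)
    mx <- apply(gc, 2L, max)
    mx[mx == 0] <- 1
    G[[child]] <- sweep(gc, 2L, mx, "/")
  }
  internal <- (n + 1L):ntot
  states <- matrix(NA_character_, tree$Nnode, S,
                   dimnames = list(tree$node.label, NULL))
  posterior <- matrix(NA_real_, tree$Nnode, S,
                      dimnames = list(tree$node.label, NULL))
  for (node in internal) {
    post <- G[[node]] * up$partials[[node]]
    tot <- colSums(post)
    post <- sweep(post, 2L, tot, "/")
    # argmax with alphabetical tie-break, tolerant of float round-off
    best <- apply(post, 2L, function(col) {
      which(col >= max(col) * (1 - 1e-9))[1L]
    })
    lab <- tree$node.label[node - n]
    states[lab, ] <- model$states[best]
    posterior[lab, ] <- post[cbind(best, seq_len(S))]
  }
  structure(list(states = states, posterior = posterior,
                 method = "marginal-ML"), class = "ancestral_states")
}

#' Fitch parsimony ancestral states for an amino-acid alignment
#'
#' First pass builds intersection/union state sets; the second pass
#' resolves each node by inheriting the parent's state when it is in the
#' node's set, otherwise taking the alphabetically smallest member.  Gap
#' and unknown tip symbols are wildcards.  Posteriors are set to 1.
#'
#' @inheritParams marginal_ancestral_states
#' @return An `ancestral_states` object with `method = "parsimony"` and a
#'   `changes` attribute (minimum substitution count per site).
#' @export
fitch_parsimony_states <- function(tree, alignment) {
  if (is.null(tree$node.label)) tree <- canonical_tree(tree)
  if (!setequal(rownames(alignment), tree$tip.label)) {
    stop("alignment labels do not match tree tips")
  }
  aa <- amino_acids()
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  S <- ncol(alignment)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  p <- parent_vector(tree)
  states <- matrix(NA_character_, tree$Nnode, S,
                   dimnames = list(tree$node.label, NULL))
  changes <- integer(S)
  # per-site set representation: logical k-vector per node
  sets <- array(FALSE, c(ntot, 20L, S))
  for (i in seq_len(n)) {
    chars <- alignment[tree$tip.label[i], ]
    hit <- match(chars, aa)
    for (s in seq_len(S)) {
      if (is.na(hit[s])) sets[i, , s] <- TRUE else sets[i, hit[s], s] <- TRUE
    }
  }
  internal_po <- unique(po$edge[, 1L])
  for (s in seq_len(S)) {
    nch <- 0L
    for (node in internal_po) {
      cs <- sets[kids[[as.character(node)]], , s, drop = FALSE]
      inter <- apply(cs, 2L, all)
      if (any(inter)) {
        sets[node, , s] <- inter
      } else {
        sets[node, , s] <- apply(cs, 2L, any)
        nch <- nch + 1L
      }
    }
    changes[s] <- nch
  }
  node_state <- matrix(NA_character_, ntot, S)
  root <- n + 1L
  for (s in seq_len(S)) {
    node_state[root, s] <- aa[which(sets[root, , s])[1L]]
  }
  for (i in rev(seq_len(nrow(po$edge)))) {  # preorder
    parent <- po$edge[i, 1L]; child <- po$edge[i, 2L]
    for (s in seq_len(S)) {
      ps <- node_state[parent, s]
      node_state[child, s] <- if (sets[child, match(ps, aa), s]) ps else
        aa[which(sets[child, , s])[1L]]
    }
  }
  states[] <- node_state[(n + 1L):ntot, , drop = FALSE]
  rownames(states) <- tree$node.label
  posterior <- matrix(1, tree$Nnode, S, dimnames = dimnames(states))
  structure(list(states = states, posterior = posterior,
                 method = "parsimony", changes = changes),
            class = "ancestral_states")
}

#' Read externally supplied ancestral states
#'
#' @param path TSV with columns `node_id`, `site`, `state`, `posterior`.
#' @param tree The `phylo` whose node labels the `node_id` column uses.
#' @param n_sites Number of alignment sites.
#' @return An `ancestral_states` object with `method = "supplied"`.
#' @export
read_ancestral_states <- function(path, tree, n_sites) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "site", "state", "posterior") %in% names(d)))
  states <- matrix(NA_character_, tree$Nnode, n_sites,
                   dimnames = list(tree$node.label, NULL))
  posterior <- matrix(NA_real_, tree$Nnode, n_sites,
                      dimnames = list(tree$node.label, NULL))
  states[cbind(d$node_id, d$site)] <- toupper(d$state)
  posterior[cbind(d$node_id, d$site)] <- d$posterior
  if (any(posterior < 0 | posterior > 1, na.rm = TRUE)) {
    stop("posterior outside [0, 1]")
  }
  structure(list(states = states, posterior = posterior, method = "supplied"),
            class = "ancestral_states")
}

#' Count convergent and divergent substitutions for one tip pair
#'
#' Per site with reconstructed MRCA state m (posterior >= `posterior_floor`)
#' and non-gap, non-ambiguous tip states `s_a`, `s_b`:
#' convergent iff `s_a == s_b != m`; divergent iff `s_a != s_b` and (under
#' the default `"both_changed"` rule) both differ from m.  Other patterns
#' (including single-lineage changes) count as neither.
#'
#' @param states An `ancestral_states` object covering the pair's MRCA.
#' @param alignment Character matrix of observed tip sequences.
#' @param tree A `phylo` with canonical node labels.
#' @param tip_a,tip_b Distinct tip labels.
#' @param posterior_floor Minimum MRCA posterior for a site to be scored
#'   (default 0: no filter).
#' @param divergent_rule `"both_changed"` (default) or `"any_different"`
#'   (divergent whenever the tips differ, regardless of the MRCA state).
#' @return Named integer vector `c(C = ..., D = ...)`.
#' @export
count_pair_substitutions <- function(states, alignment, tree, tip_a, tip_b,
                                     posterior_floor = 0,
                                     divergent_rule = c("both_changed",
                                                        "any_different")) {
  divergent_rule <- match.arg(divergent_rule)
  if (identical(tip_a, tip_b)) stop("tips must be distinct")
  mrca <- mrca_node(tree, tip_a, tip_b)
  lab <- tree$node.label[mrca - ape::Ntip(tree)]
  m <- states$states[lab, ]
  pp <- states$posterior[lab, ]
  sa <- alignment[tip_a, ]
  sb <- alignment[tip_b, ]
  aa <- amino_acids()
  ok <- (sa %in% aa) & (sb %in% aa) & (m %in% aa) & !is.na(pp) &
    pp >= posterior_floor
  conv <- ok & sa == sb & sa != m
  div <- if (divergent_rule == "both_changed") {
    ok & sa != sb & sa != m & sb != m
  } else {
    ok & sa != sb
  }
  c(C = sum(conv), D = sum(div))
}

#' Build the pairwise convergence table over all genes
#'
#' One record per unordered tip pair, with convergent (`C`) and divergent
#' (`D`) counts summed over genes, divergence time, MRCA id, and focal
#' flags.  A pair is plunge-focal iff both tips plunge-dive and the Fitch
#' reconstruction of the trait puts their MRCA in the non-plunge state
#' (independent origins); island-focal analogously.
#'
#' @param tree Ultrametric species `phylo` with canonical node labels.
#' @param states_by_gene Named list of `ancestral_states`, one per gene.
#' @param alignments Named list of alignments matching `states_by_gene`.
#' @param trait_map Trait data frame (see [read_trait_table()]).
#' @param response `"total"` (default) for genome-wide C, or `"per_gene"`
#'   for C divided by the number of scored genes.
#' @param posterior_floor Passed to [count_pair_substitutions()].
#' @param divergent_rule Passed to [count_pair_substitutions()].
#' @return Data frame with one row per pair: `a`, `b`, `mrca_id`,
#'   `divergence_time`, `C`, `D`, `plunge_focal`, `island_focal`,
#'   `n_genes`, `response`.
#' @export
build_pair_table <- function(tree, states_by_gene, alignments, trait_map,
                             response = c("total", "per_gene"),
                             posterior_floor = 0,
                             divergent_rule = "both_changed") {
  response <- match.arg(response)
  stopifnot(length(states_by_gene) >= 1L,
            identical(names(states_by_gene), names(alignments)))
  trait_map <- validate_trait_map(as.data.frame(trait_map), tree)
  keep <- vapply(alignments, function(a) all(tree$tip.label %in% rownames(a)),
                 logical(1))
  if (any(!keep)) {
    warning("skipping gene(s) with missing tips: ",
            paste(names(alignments)[!keep], collapse = ", "))
  }
  genes <- names(alignments)[keep]
  if (length(genes) == 0L) stop("no usable genes")
  pairs <- enumerate_pairs(tree$tip.label)
  n <- ape::Ntip(tree)
  plunge <- stats::setNames(trait_map$plunge, trait_map$species)
  island <- stats::setNames(trait_map$island, trait_map$species)
  fit_p <- fitch_binary_trait(tree, plunge)
  fit_i <- fitch_binary_trait(tree, island)
  C <- D <- integer(nrow(pairs))
  mrca_id <- character(nrow(pairs))
  tdiv <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    mn <- mrca_node(tree, a, b)
    mrca_id[i] <- tree$node.label[mn - n]
    tdiv[i] <- divergence_time(tree, a, b)
    for (g in genes) {
      cd <- count_pair_substitutions(states_by_gene[[g]], alignments[[g]],
                                     tree, a, b, posterior_floor,
                                     divergent_rule)
      C[i] <- C[i] + cd[["C"]]
      D[i] <- D[i] + cd[["D"]]
    }
  }
  mrca_idx <- node_index(tree, mrca_id)
  plunge_focal <- as.integer(plunge[pairs$a] == 1 & plunge[pairs$b] == 1 &
                               fit_p$states[mrca_idx] == 0L)
  island_focal <- as.integer(island[pairs$a] == 1 & island[pairs$b] == 1 &
                               fit_i$states[mrca_idx] == 0L)
  resp <- if (response == "total") C else C / length(genes)
  data.frame(a = pairs$a, b = pairs$b, mrca_id = mrca_id,
             divergence_time = tdiv, C = C, D = D,
             plunge_focal = plunge_focal, island_focal = island_focal,
             n_genes = length(genes), response = resp,
             stringsAsFactors = FALSE)
}
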