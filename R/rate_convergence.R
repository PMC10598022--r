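# Simplified relative-evolutionary-rate scan: per-gene branch rates are
# residuals of sqrt-transformed gene branch lengths regressed on master
# branch lengths; convergent shifts on foreground branches are scored by a
# rank-sum statistic with parametric and permulation p-values.

# key a branch by the sorted tip set it subtends
clade_keys <- function(tree) {
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tipsets <- vector("list", ntot)
  for (i in seq_len(n)) tipsets[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(po$edge))) {
    parent <- po$edge[r, 1L]; child <- po$edge[r, 2L]
    tipsets[[parent]] <- c(tipsets[[parent]], tipsets[[child]])
  }
  vapply(tree$edge[, 2L], function(node) {
    paste(sort(tipsets[[node]]), collapse = "|")
  }, character(1))
}

#' Relative evolutionary rates per branch and gene
#'
#' For each gene tree, branch lengths are paired with the master tree's
#' over shared branches (matched by subtended tip set, master length >=
#' `min_branch_length`), both sqrt-transformed, and the gene's relative
#' rates are the residuals of the least-squares regression of gene on
#' master lengths, column-centered.  Genes with fewer than 5 shared
#' branches are skipped with a warning.
#'
#' @param gene_trees Named list of `phylo` objects (substitution branch
#'   lengths), topologically compatible with `master_tree`.
#' @param master_tree Master `phylo`.
#' @param min_branch_length Master-branch floor (default 1e-6).
#' @return An `rer_matrix`: branch x gene matrix (rows indexed by master
#'   edge, `NA` where a gene lacks a branch) with the master edge table in
#'   attributes.
#' @export
compute_rers <- function(gene_trees, master_tree, min_branch_length = 1e-6) {
  mk <- clade_keys(master_tree)
  usable <- master_tree$edge.length >= min_branch_length
  R <- matrix(NA_real_, nrow(master_tree$edge), length(gene_trees),
              dimnames = list(paste0("e", seq_along(mk)), names(gene_trees)))
  skipped <- character(0)
  for (g in names(gene_trees)) {
    gt <- gene_trees[[g]]
    gk <- clade_keys(gt)
    hit <- match(mk, gk)
    shared <- which(!is.na(hit) & usable)
    if (length(shared) < 5L) {
      skipped <- c(skipped, g)
      next
    }
    x <- sqrt(master_tree$edge.length[shared])
    y <- sqrt(gt$edge.length[hit[shared]])
    res <- stats::lm.fit(cbind(1, x), y)$residuals
    R[shared, g] <- res - mean(res)
  }
  if (length(skipped)) {
    warning("skipped gene(s) with < 5 shared branches: ",
            paste(skipped, collapse = ", "))
  }
  attr(R, "master_edge") <- master_tree$edge
  class(R) <- c("rer_matrix", class(R))
  R
}

# standardized rank-sum score of foreground vs background values
ranksum_z <- function(values, is_fg) {
  ok <- !is.na(values)
  v <- values[ok]; fg <- is_fg[ok]
  n1 <- sum(fg); n2 <- sum(!fg)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  r <- rank(v)
  W <- sum(r[fg])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sd <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  if (sd == 0) return(0)
  (W - mu) / sd
}

#' Branches carrying a foreground phenotype
#'
#' Edges on the paths from each trait origin to its foreground tips,
#' including the stem branch of each maximal foreground clade (the branch
#' on which the trait arose).
#'
#' @param tree A `phylo`.
#' @param foreground_tips Character vector of foreground tip labels.
#' @return Integer vector of edge indices into `tree$edge`.
#' @export
foreground_branch_set <- function(tree, foreground_tips) {
  n <- ape::Ntip(tree)
  fg <- tree$tip.label %in% foreground_tips
  ntot <- n + tree$Nnode
  allfg <- logical(ntot)
  allfg[seq_len(n)] <- fg
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    allfg[node] <- all(allfg[kids[[as.character(node)]]])
  }
  which(allfg[tree$edge[, 2L]])
}

#' Foreground rate-shift statistic per gene
#'
#' Wilcoxon rank-sum standardized score of foreground vs background
#' relative rates (positive = foreground acceleration) with a parametric
#' normal-approximation p-value (tie-corrected).
#'
#' @param rers An `rer_matrix` from [compute_rers()].
#' @param foreground_branches Integer edge indices (e.g. from
#'   [foreground_branch_set()]).
#' @return Data frame: `gene`, `stat`, `p_param` (`NA` where a gene lacks
#'   2 foreground or 2 background branches with data).
#' @export
foreground_association <- function(rers, foreground_branches) {
  is_fg <- seq_len(nrow(rers)) %in% foreground_branches
  if (sum(is_fg) < 2L || sum(!is_fg) < 2L) {
    stop("need >= 2 foreground and >= 2 background branches")
  }
  stat <- apply(rers, 2L, ranksum_z, is_fg = is_fg)
  data.frame(gene = colnames(rers), stat = stat,
             p_param = 2 * stats::pnorm(-abs(stat)), row.names = NULL)
}

#' Permulation p-values for convergent rate shifts
#'
#' Builds the null distribution of the foreground statistic by permulating
#' the binary trait on the tree `n_perm` times (each permuted tip set is
#' converted to a foreground branch set) and reports per-gene empirical
#' p-values \eqn{(1 + \#\{|stat_{perm}| \ge |stat_{obs}|\}) / (n_{perm}+1)}
#' (or one-sided variants) with BH q-values.
#'
#' @param rers An `rer_matrix`.
#' @param trait_map Trait data frame; `trait` picks the binary column.
#' @param tree `phylo` matching the RER master tree.
#' @param n_perm Number of permulations (default 500, >= 99).
#' @param seed Optional integer seed.
#' @param side `"two"` (default), `"greater"` (acceleration) or `"less"`.
#' @param trait Trait column (default `"plunge"`).
#' @param match_origins Passed to [permulate_binary()].
#' @return Data frame: `gene`, `stat`, `p_param`, `p_perm`, `q`.
#' @export
permulation_pvalues <- function(rers, trait_map, tree, n_perm = 500,
                                seed = NULL, side = c("two", "greater", "less"),
                                trait = "plunge", match_origins = FALSE) {
  side <- match.arg(side)
  if (n_perm < 99) stop("n_perm must be >= 99")
  trait_map <- as.data.frame(trait_map)
  fg_tips <- trait_map$species[trait_map[[trait]] == 1]
  obs <- foreground_association(rers, foreground_branch_set(tree, fg_tips))
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fg <- permulate_binary(tree, fg_tips, match_origins = match_origins)
      is_fg <- seq_len(nrow(rers)) %in% foreground_branch_set(tree, fg)
      apply(rers, 2L, ranksum_z, is_fg = is_fg)
    }, numeric(ncol(rers)))
  })
  perm_stats <- matrix(perm_stats, nrow = ncol(rers))
  p_perm <- vapply(seq_len(ncol(rers)), function(gi) {
    s <- obs$stat[gi]
    if (is.na(s)) return(NA_real_)
    null <- perm_stats[gi, ]
    null <- null[!is.na(null)]
    hits <- switch(side,
                   two = sum(abs(null) >= abs(s)),
                   greater = sum(null >= s),
                   less = sum(null <= s))
    (1 + hits) / (length(null) + 1)
  }, numeric(1))
  obs$p_perm <- p_perm
  obs$q <- NA_real_
  ok <- !is.na(p_perm)
  if (any(ok)) obs$q[ok] <- bh_fdr(p_perm[ok])
  obs
}
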