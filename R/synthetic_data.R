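# Generators for every input the pipeline consumes, with controllable
# effect sizes and truth objects emitted alongside the data so downstream
# recovery can be checked against a known ground truth.  Every generator
# is a pure function of its arguments and seed.

#' Simulate an ultrametric Yule tree with convergent binary traits
#'
#' Draws a pure-birth tree scaled to height 1, places exactly
#' `n_origins_plunge` (and `n_origins_island`) trait origins on pairwise
#' non-nested edges chosen uniformly, marks all descendant tips as
#' foreground, and simulates ln body mass by Brownian motion.
#'
#' @param n_tips Number of tips (>= 8; the motivating kingfisher system has 31).
#' @param yule_rate Birth rate of the Yule process (default 1; height is
#'   rescaled to 1 regardless).
#' @param n_origins_plunge,n_origins_island Exact origin counts (defaults
#'   4 and 5, the study's observed counts).
#' @param mass_baseline Root ln-mass (default 4, about 55 g).
#' @param mass_sigma2 Brownian rate for ln-mass (default 0.5).
#' @param seed Optional integer seed.
#' @param max_tries Retries for non-nested origin placement per topology.
#' @return List: `tree` (canonical `phylo`), `traits` (trait_map data
#'   frame), `origin_edges` (list of edge indices per trait).
#' @export
simulate_tree_and_traits <- function(n_tips = 31, yule_rate = 1,
                                     n_origins_plunge = 4,
                                     n_origins_island = 5,
                                     mass_baseline = 4, mass_sigma2 = 0.5,
                                     seed = NULL, max_tries = 200) {
  stopifnot(n_tips >= 8)
  with_seed(seed, {
    for (topo_try in 1:50) {
      tr <- ape::rphylo(n_tips, birth = yule_rate, death = 0)
      tr$edge.length <- tr$edge.length / tree_height(tr)
      tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
      tr <- canonical_tree(tr)
      pl <- place_origins(tr, n_origins_plunge, max_tries)
      is <- place_origins(tr, n_origins_island, max_tries)
      if (is.null(pl) || is.null(is)) next
      mass <- mass_baseline + simulate_bm(tr, mass_sigma2)
      traits <- validate_trait_map(data.frame(
        species = tr$tip.label,
        plunge = as.integer(tr$tip.label %in% pl$tips),
        island = as.integer(tr$tip.label %in% is$tips),
        mass = as.numeric(mass[tr$tip.label])), tr)
      return(list(tree = tr, traits = traits,
                  origin_edges = list(plunge = pl$edges, island = is$edges)))
    }
    stop("could not place non-nested origins; lower the origin count")
  })
}

# sample k pairwise non-ancestral edges whose clades are recovered as
# exactly k origins by parsimony; NULL if max_tries exhausted
place_origins <- function(tree, k, max_tries) {
  if (k == 0L) return(list(edges = integer(0), tips = character(0)))
  n <- ape::Ntip(tree)
  keys <- clade_keys(tree)
  clades <- strsplit(keys, "|", fixed = TRUE)
  for (try in seq_len(max_tries)) {
    edges <- sample(nrow(tree$edge), k)
    tipsets <- clades[edges]
    sizes <- lengths(tipsets)
    fg <- unique(unlist(tipsets))
    if (length(fg) != sum(sizes)) next          # nested or overlapping
    if (length(fg) >= n - 1L) next              # keep a background
    trait <- stats::setNames(as.integer(tree$tip.label %in% fg),
                             tree$tip.label)
    if (fitch_binary_trait(tree, trait)$origins != k) next
    if (count_foreground_clades(tree, fg) != k) next
    return(list(edges = edges, tips = fg))
  }
  NULL
}

# Gillespie simulation of the equal-rates model along one branch for a
# vector of site states (integer codes 1..20); leaving rate 1 per unit
# branch length, jumps uniform among the other 19 states
evolve_states <- function(states, t) {
  n_events <- stats::rpois(length(states), t)
  for (i in which(n_events > 0L)) {
    s <- states[i]
    for (e in seq_len(n_events[i])) {
      s <- sample((1:20)[-s], 1L)
    }
    states[i] <- s
  }
  states
}

#' Simulate an amino-acid alignment with convergent foreground sites
#'
#' Background sites evolve under the equal-rates 20-state model (Gillespie
#' simulation along branches, recording true node states).  A fraction of
#' sites is convergent: on foreground branches only, the end-of-branch
#' state is replaced by a site-specific target amino acid with probability
#' `attraction`; inheritance then proceeds normally, creating an excess of
#' convergent substitutions among independently foreground lineages.
#'
#' @param tree Canonical `phylo` (height 1).
#' @param trait_map Trait data frame; the `plunge` column defines the
#'   foreground.
#' @param n_sites Sites per gene (default 200).
#' @param convergent_fraction Fraction of convergent sites (default 0.05).
#' @param attraction Per-foreground-branch replacement probability
#'   (default 0.5).
#' @param rate Expected substitutions per site over the tree height
#'   (default 0.2).
#' @param seed Optional integer seed.
#' @return List: `alignment` (tips x sites character matrix), `truth`
#'   (list with internal `node_states`, `site_class`, `target`).
#' @export
simulate_alignment_with_convergence <- function(tree, trait_map,
                                                n_sites = 200,
                                                convergent_fraction = 0.05,
                                                attraction = 0.5,
                                                rate = 0.2, seed = NULL) {
  aa <- amino_acids()
  n <- ape::Ntip(tree)
  ntot <- n + tree$Nnode
  trait_map <- as.data.frame(trait_map)
  fg_tips <- trait_map$species[trait_map$plunge == 1]
  fg_edges <- foreground_branch_set(tree, fg_tips)
  with_seed(seed, {
    n_conv <- round(convergent_fraction * n_sites)
    site_class <- rep("background", n_sites)
    if (n_conv > 0L) site_class[sample(n_sites, n_conv)] <- "convergent"
    target <- ifelse(site_class == "convergent",
                     sample(20L, n_sites, replace = TRUE), NA_integer_)
    states <- matrix(NA_integer_, ntot, n_sites)
    root <- n + 1L
    states[root, ] <- sample(20L, n_sites, replace = TRUE)
    po <- ape::reorder.phylo(tree, "postorder")
    conv_idx <- which(site_class == "convergent")
    for (i in rev(seq_len(nrow(po$edge)))) {   # preorder
      parent <- po$edge[i, 1L]; child <- po$edge[i, 2L]
      t_sub <- po$edge.length[i] * rate
      s <- evolve_states(states[parent, ], t_sub)
      edge_id <- which(tree$edge[, 1L] == parent & tree$edge[, 2L] == child)
      if (edge_id %in% fg_edges && length(conv_idx)) {
        hit <- conv_idx[stats::runif(length(conv_idx)) < attraction]
        s[hit] <- target[hit]
      }
      states[child, ] <- s
    }
    alignment <- matrix(aa[states[seq_len(n), ]], n, n_sites,
                        dimnames = list(tree$tip.label, NULL))
    node_states <- matrix(aa[states[(n + 1L):ntot, ]], tree$Nnode, n_sites,
                          dimnames = list(tree$node.label, NULL))
    list(alignment = alignment,
         truth = list(node_states = node_states, site_class = site_class,
                      target = ifelse(is.na(target), NA_character_,
                                      aa[target])))
  })
}

#' Simulate alignments and reconstructed states for many genes
#'
#' Convenience wrapper producing the inputs of [build_pair_table()].
#'
#' @inheritParams simulate_alignment_with_convergence
#' @param n_genes Number of genes (default 50).
#' @param reconstruction `"truth"` (use the generator's true node states),
#'   `"ml"` or `"parsimony"`.
#' @param ... Passed to [simulate_alignment_with_convergence()].
#' @return List with `alignments`, `states` (both named by gene) and
#'   `truth` per gene.
#' @export
simulate_gene_alignments <- function(tree, trait_map, n_genes = 50,
                                     reconstruction = c("truth", "ml",
                                                        "parsimony"),
                                     seed = NULL, ...) {
  reconstruction <- match.arg(reconstruction)
  with_seed(seed, {
    out <- lapply(seq_len(n_genes), function(g) {
      simulate_alignment_with_convergence(tree, trait_map, ...)
    })
    names(out) <- sprintf("gene%03d", seq_len(n_genes))
    alignments <- lapply(out, `[[`, "alignment")
    states <- lapply(out, function(x) {
      switch(reconstruction,
             truth = structure(list(states = x$truth$node_states,
                                    posterior = matrix(
                                      1, nrow(x$truth$node_states),
                                      ncol(x$truth$node_states),
                                      dimnames = dimnames(x$truth$node_states)),
                                    method = "supplied"),
                               class = "ancestral_states"),
             ml = marginal_ancestral_states(tree, x$alignment),
             parsimony = fitch_parsimony_states(tree, x$alignment))
    })
    list(alignments = alignments, states = states,
         truth = lapply(out, `[[`, "truth"))
  })
}

#' Simulate island/continental Ne trajectory regimes
#'
#' Per species, log-Ne on a log-spaced time grid is a baseline plus a
#' random walk whose total standard deviation depends on the regime
#' (island > continental), with an island-only linear (in log-time)
#' decline over the most recent decade of the grid so that island species
#' end with reduced present-day Ne.  The walk increments are
#' phylogenetically correlated across species (Brownian tip correlation),
#' matching the covariance assumption of the downstream phylogenetic
#' regression: closely related species have similar demographic histories.
#'
#' @param tree Canonical `phylo`.
#' @param trait_map Trait data frame; `island` defines the regime.
#' @param baseline_log_ne Baseline natural-log Ne (default `log(5e5)`).
#' @param sd_island,sd_continental Total fluctuation SD of the walk
#'   (defaults 1.0 and 0.4).
#' @param decline_island Fractional present-day Ne reduction for island
#'   species (default 0.9: present Ne is a tenth of the undisturbed
#'   level, an order-of-magnitude crash).
#' @param t_min,t_max Grid span in years (defaults 1e3, 1e7).
#' @param n_points Grid size (default 64).
#' @param seed Optional integer seed.
#' @return Named list of [ne_trajectory()] objects.
#' @export
simulate_ne_trajectories <- function(tree, trait_map,
                                     baseline_log_ne = log(5e5),
                                     sd_island = 1.0, sd_continental = 0.4,
                                     decline_island = 0.9,
                                     t_min = 1e3, t_max = 1e7,
                                     n_points = 64, seed = NULL) {
  trait_map <- as.data.frame(trait_map)
  grid <- exp(seq(log(t_min), log(t_max), length.out = n_points))
  sp <- trait_map$species
  C <- phylo_covariance(tree, sp)
  C <- C / max(diag(C))                       # Brownian tip correlation
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(sp))
  sd_tot <- ifelse(trait_map$island == 1, sd_island, sd_continental)
  with_seed(seed, {
    # correlated standard-normal increments: species x time
    Z <- L %*% matrix(stats::rnorm(length(sp) * n_points), length(sp))
    steps <- Z * (sd_tot / sqrt(n_points))
    out <- lapply(seq_len(nrow(trait_map)), function(i) {
      walk <- cumsum(steps[i, ])
      logne <- baseline_log_ne + rev(walk)    # walk anchored in the past
      if (trait_map$island[i] == 1 && decline_island > 0) {
        w <- pmax(0, 1 - log10(grid / t_min))  # 1 at t_min, 0 beyond 10*t_min
        logne <- logne + w * log(1 - decline_island)
      }
      ne_trajectory(sp[i], grid, exp(logne))
    })
    names(out) <- sp
    out
  })
}

#' Simulate gene-test tables, PSG counts and a term map with planted truth
#'
#' Plants `n_planted` adaptively-convergent genes that pass all four
#' selection/convergence tests; the remaining genes receive uniform null
#' p-values and sub-threshold posteriors.  Per-species PSG totals are
#' drawn log-normally with log-mean
#' `b0 + b_plunge plunge + b_mass mass + b_island island + b_int mass x island`,
#' and each species' PSG set contains the planted genes when the species
#' plunge-dives (creating overlap structure among focal pairs).  One term
#' of the emitted term map covers exactly the planted subset.
#'
#' @param tree Canonical `phylo`.
#' @param trait_map Trait data frame.
#' @param n_genes Gene universe size (default 200).
#' @param n_planted Planted adaptively-convergent genes (default 20).
#' @param b0,b_plunge,b_mass,b_island,b_int PSG log-mean coefficients
#'   (defaults 4.5, 0.4, -0.15, 0.6, -0.2).
#' @param dispersion SD of the log-normal noise on totals (default 0.25).
#' @param n_terms Number of random extra terms in the term map
#'   (default 10).
#' @param seed Optional integer seed.
#' @return List: `gene_tests` (data frame across the four tests),
#'   `psg_table`, `term_map`, `background`, `planted`, `totals_expected`.
#' @export
simulate_gene_tests_and_psgs <- function(tree, trait_map, n_genes = 200,
                                         n_planted = 20, b0 = 4.5,
                                         b_plunge = 0.4, b_mass = -0.15,
                                         b_island = 0.6, b_int = -0.2,
                                         dispersion = 0.25, n_terms = 10,
                                         seed = NULL) {
  trait_map <- as.data.frame(trait_map)
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted <- genes[seq_len(n_planted)]
  nulls <- setdiff(genes, planted)
  plunge_sp <- trait_map$species[trait_map$plunge == 1]
  with_seed(seed, {
    sig_p <- function(m) stats::runif(m, 0, 1e-4)
    null_p <- function(m) stats::runif(m)
    gene_tests <- rbind(
      data.frame(gene_id = genes, test_name = "branch_site",
                 branch_id = NA_character_,
                 score = c(sig_p(n_planted), null_p(n_genes - n_planted))),
      data.frame(gene_id = genes, test_name = "relax",
                 branch_id = NA_character_,
                 score = c(sig_p(n_planted), null_p(n_genes - n_planted))),
      data.frame(gene_id = genes, test_name = "residue_convergence",
                 branch_id = NA_character_,
                 score = c(stats::runif(n_planted, 0.85, 1),
                           stats::runif(n_genes - n_planted, 0, 0.75))),
      do.call(rbind, lapply(plunge_sp, function(sp) {
        data.frame(gene_id = genes, test_name = "branch_adaptive",
                   branch_id = sp,
                   score = c(sig_p(n_planted),
                             null_p(n_genes - n_planted)))
      })))
    gene_tests$qvalue <- NA_real_
    gene_tests <- validate_gene_tests(gene_tests)
    # per-species PSG totals with covariate effects
    lmu <- b0 + b_plunge * trait_map$plunge + b_mass * trait_map$mass +
      b_island * trait_map$island + b_int * trait_map$mass * trait_map$island
    totals <- pmin(n_genes,
                   pmax(n_planted + 1L,
                        round(exp(lmu + stats::rnorm(nrow(trait_map), 0,
                                                     dispersion)))))
    M <- matrix(0L, nrow(trait_map), n_genes,
                dimnames = list(trait_map$species, genes))
    for (i in seq_len(nrow(trait_map))) {
      base <- if (trait_map$plunge[i] == 1) planted else character(0)
      extra <- sample(nulls, totals[i] - length(base))
      M[i, c(base, extra)] <- 1L
    }
    attr(M, "totals") <- rowSums(M)
    class(M) <- c("psg_table", class(M))
    term_map <- rbind(
      data.frame(term_id = "planted_term", gene_id = planted),
      do.call(rbind, lapply(seq_len(n_terms), function(tix) {
        data.frame(term_id = sprintf("term%02d", tix),
                   gene_id = sample(genes, 25))
      })))
    list(gene_tests = gene_tests, psg_table = M, term_map = term_map,
         background = genes, planted = planted,
         totals_expected = stats::setNames(exp(lmu), trait_map$species))
  })
}

#' Simulate per-gene trees with convergent rate shifts
#'
#' Gene trees share the master topology; branch lengths are the master's
#' times a gene-level rate and log-normal branch noise, with foreground
#' branches multiplied by `shift_factor` for a `shift_fraction` of genes.
#'
#' @param tree Canonical master `phylo`.
#' @param trait_map Trait data frame; `plunge` defines the foreground.
#' @param n_genes Number of genes (default 100).
#' @param shift_fraction Fraction of genes with a foreground shift
#'   (default 0.2).
#' @param shift_factor Foreground rate multiplier for shifted genes
#'   (default 3).
#' @param noise_sd SD of log-normal branch noise (default 0.3).
#' @param rate_sd SD of log-normal gene-level rate variation (default 0.3).
#' @param seed Optional integer seed.
#' @return List: `gene_trees` (named list of `phylo`), `shifted` (gene
#'   names with a true shift).
#' @export
simulate_gene_trees <- function(tree, trait_map, n_genes = 100,
                                shift_fraction = 0.2, shift_factor = 3,
                                noise_sd = 0.3, rate_sd = 0.3, seed = NULL) {
  trait_map <- as.data.frame(trait_map)
  fg_tips <- trait_map$species[trait_map$plunge == 1]
  fg_edges <- foreground_branch_set(tree, fg_tips)
  with_seed(seed, {
    n_shift <- round(shift_fraction * n_genes)
    shifted <- sample(n_genes, n_shift)
    gene_trees <- lapply(seq_len(n_genes), function(g) {
      gt <- tree
      rate <- exp(stats::rnorm(1, 0, rate_sd))
      mult <- exp(stats::rnorm(length(gt$edge.length), 0, noise_sd))
      len <- gt$edge.length * rate * mult
      if (g %in% shifted) len[fg_edges] <- len[fg_edges] * shift_factor
      gt$edge.length <- len
      gt
    })
    names(gene_trees) <- sprintf("gene%03d", seq_len(n_genes))
    list(gene_trees = gene_trees, shifted = names(gene_trees)[shifted])
  })
}

#' Simulate a pair table directly from the convergence mixed model
#'
#' Generates pair records on a given tree with known fixed effects and
#' variance components, for calibration and parameter-recovery checks of
#' [fit_pair_lmm()]: divergent counts and times come from the tree, and
#' the response is built as
#' `X beta + u_a + u_b + u_mrca + e` with `u_mrca` drawn from the
#' phylogenetic covariance of the MRCA nodes.
#'
#' @param tree Canonical ultrametric `phylo`.
#' @param trait_map Trait data frame.
#' @param beta Named fixed effects (intercept, divergent, time, plunge,
#'   island, divergent_x_time).
#' @param s_lineage,s_mrca,s_resid Variance components (defaults 0.5, 1,
#'   1).
#' @param mean_D Mean divergent count scale (default 50).
#' @param seed Optional integer seed.
#' @return Pair-record data frame ready for [fit_pair_lmm()].
#' @export
simulate_pair_table <- function(tree, trait_map,
                                beta = c(intercept = 0, divergent = 0.3,
                                         time = 0.5, plunge = 0, island = 0,
                                         divergent_x_time = 0),
                                s_lineage = 0.5, s_mrca = 1, s_resid = 1,
                                mean_D = 50, seed = NULL) {
  trait_map <- validate_trait_map(as.data.frame(trait_map), tree)
  pairs <- enumerate_pairs(tree$tip.label)
  n <- nrow(pairs)
  ntip <- ape::Ntip(tree)
  plunge <- stats::setNames(trait_map$plunge, trait_map$species)
  island <- stats::setNames(trait_map$island, trait_map$species)
  fit_p <- fitch_binary_trait(tree, plunge)
  fit_i <- fitch_binary_trait(tree, island)
  mrca_idx <- vapply(seq_len(n), function(i) {
    mrca_node(tree, pairs$a[i], pairs$b[i])
  }, integer(1))
  mrca_id <- tree$node.label[mrca_idx - ntip]
  tdiv <- vapply(seq_len(n), function(i) {
    divergence_time(tree, pairs$a[i], pairs$b[i])
  }, numeric(1))
  plunge_focal <- as.integer(plunge[pairs$a] == 1 & plunge[pairs$b] == 1 &
                               fit_p$states[mrca_idx] == 0L)
  island_focal <- as.integer(island[pairs$a] == 1 & island[pairs$b] == 1 &
                               fit_i$states[mrca_idx] == 0L)
  with_seed(seed, {
    D <- stats::rpois(n, mean_D * pmax(tdiv, 0.05))
    X <- cbind(1, D, tdiv, plunge_focal, island_focal, D * tdiv)
    # one effect per lineage, entering through both roles: the data carry
    # no role information, so role shuffling is a symmetry of the model
    lin <- sort(unique(c(pairs$a, pairs$b)))
    ua <- ub <- stats::setNames(stats::rnorm(length(lin), 0,
                                             sqrt(s_lineage)), lin)
    mlev <- sort(unique(mrca_id))
    A <- normalize_node_cov(phylo_covariance(tree, mlev))
    evA <- eigen(A, symmetric = TRUE)
    L <- evA$vectors %*% diag(sqrt(pmax(evA$values, 0)), nrow(A))
    um <- stats::setNames(sqrt(s_mrca) * drop(L %*% stats::rnorm(nrow(A))),
                          mlev)
    y <- drop(X %*% beta) + ua[pairs$a] + ub[pairs$b] + um[mrca_id] +
      stats::rnorm(n, 0, sqrt(s_resid))
    data.frame(a = pairs$a, b = pairs$b, mrca_id = mrca_id,
               divergence_time = tdiv, C = NA_integer_, D = D,
               plunge_focal = plunge_focal, island_focal = island_focal,
               n_genes = NA_integer_, response = y,
               stringsAsFactors = FALSE)
  })
}
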