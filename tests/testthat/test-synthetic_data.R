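test_that("trait origins are exact, non-nested and recoverable", {
  for (r in 1:5) {
    sim <- simulate_tree_and_traits(n_tips = 16, n_origins_plunge = 4,
                                    n_origins_island = 5, seed = r)
    tr <- sim$tree
    plunge <- stats::setNames(sim$traits$plunge, sim$traits$species)
    expect_equal(fitch_binary_trait(tr, plunge)$origins, 4L)
    island <- stats::setNames(sim$traits$island, sim$traits$species)
    expect_equal(fitch_binary_trait(tr, island)$origins, 5L)
    # origin edges pairwise non-ancestral: their clades are disjoint
    edges <- sim$origin_edges$plunge
    clades <- lapply(edges, function(e) {
      node <- tr$edge[e, 2L]
      if (node <= ape::Ntip(tr)) tr$tip.label[node]
      else ape::extract.clade(tr, node)$tip.label
    })
    tips <- unlist(clades)
    expect_equal(length(tips), length(unique(tips)))
    expect_equal(abs(tree_height_of(tr) - 1), 0, tolerance = 1e-8)
  }
  sim0 <- simulate_tree_and_traits(n_tips = 10, n_origins_plunge = 0,
                                   n_origins_island = 0, seed = 9)
  expect_true(all(sim0$traits$plunge == 0))
})

test_that("generators are pure functions of their seed", {
  s1 <- simulate_tree_and_traits(n_tips = 10, seed = 4,
                                 n_origins_plunge = 2, n_origins_island = 2)
  s2 <- simulate_tree_and_traits(n_tips = 10, seed = 4,
                                 n_origins_plunge = 2, n_origins_island = 2)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$traits, s2$traits)
  a1 <- simulate_alignment_with_convergence(s1$tree, s1$traits, seed = 5,
                                            n_sites = 40)
  a2 <- simulate_alignment_with_convergence(s1$tree, s1$traits, seed = 5,
                                            n_sites = 40)
  expect_identical(a1, a2)
  t1 <- simulate_ne_trajectories(s1$tree, s1$traits, seed = 6)
  t2 <- simulate_ne_trajectories(s1$tree, s1$traits, seed = 6)
  expect_identical(t1, t2)
})

test_that("full attraction forces every foreground tip to the target", {
  sim <- simulate_tree_and_traits(n_tips = 10, n_origins_plunge = 3,
                                  n_origins_island = 2, seed = 14)
  g <- simulate_alignment_with_convergence(sim$tree, sim$traits,
                                           n_sites = 30,
                                           convergent_fraction = 1,
                                           attraction = 1, seed = 15)
  fg <- sim$traits$species[sim$traits$plunge == 1]
  for (s in seq_len(30)) {
    expect_true(all(g$alignment[fg, s] == g$truth$target[s]))
  }
})

test_that("zero attraction reproduces the background site-pattern law", {
  tr <- random_tree(5, 99)
  tm <- data.frame(species = tr$tip.label,
                   plunge = c(1, 1, 0, 0, 1), island = 0, mass = 4)
  a_conv <- simulate_alignment_with_convergence(tr, tm, n_sites = 5000,
                                                convergent_fraction = 1,
                                                attraction = 0, seed = 16)
  a_bg <- simulate_alignment_with_convergence(tr, tm, n_sites = 5000,
                                              convergent_fraction = 0,
                                              seed = 17)
  pat <- function(aln) apply(aln, 2, function(col) {
    paste(match(col, unique(col)), collapse = "")  # shape of the pattern
  })
  p1 <- pat(a_conv$alignment); p2 <- pat(a_bg$alignment)
  cats <- names(sort(table(c(p1, p2)), decreasing = TRUE))
  top <- utils::head(cats, 12)
  f <- function(p) {
    x <- factor(ifelse(p %in% top, p, "other"), levels = c(top, "other"))
    table(x)
  }
  chi <- suppressWarnings(stats::chisq.test(rbind(f(p1), f(p2))))
  expect_gt(chi$p.value, 0.01)
})

test_that("the generator's defining property: focal pairs gain C at matched D", {
  diffs <- sapply(1:20, function(r) {
    sim <- simulate_tree_and_traits(n_tips = 12, n_origins_plunge = 3,
                                    n_origins_island = 3, seed = 1000 + r)
    ga <- simulate_gene_alignments(sim$tree, sim$traits, n_genes = 6,
                                   n_sites = 120, seed = 2000 + r,
                                   reconstruction = "truth")
    pt <- build_pair_table(sim$tree, ga$states, ga$alignments, sim$traits)
    if (sum(pt$plunge_focal) < 2) return(NA_real_)
    # compare C/D between focal and non-focal pairs (rate at matched D)
    mean(pt$C[pt$plunge_focal == 1] / pmax(pt$D[pt$plunge_focal == 1], 1)) -
      mean(pt$C[pt$plunge_focal == 0] / pmax(pt$D[pt$plunge_focal == 0], 1))
  })
  expect_gt(mean(diffs > 0, na.rm = TRUE), 0.9)
})

test_that("island trajectories crash toward the present by construction", {
  crashes <- sapply(1:20, function(r) {
    sim <- simulate_tree_and_traits(n_tips = 12, n_origins_plunge = 2,
                                    n_origins_island = 3, seed = 3000 + r)
    traj <- simulate_ne_trajectories(sim$tree, sim$traits,
                                     decline_island = 0.9, seed = 4000 + r)
    cm <- common_grid(traj)
    isl <- sim$traits$species[sim$traits$island == 1]
    mean(cm[isl, 1]) < mean(cm[setdiff(rownames(cm), isl), 1])
  })
  expect_true(all(crashes))
})

test_that("planted gene-test structure feeds the whole selection pipeline", {
  sim <- simulate_tree_and_traits(n_tips = 14, n_origins_plunge = 3,
                                  n_origins_island = 3, seed = 26)
  gs <- simulate_gene_tests_and_psgs(sim$tree, sim$traits, seed = 27)
  out <- adaptive_convergent_set(gs$gene_tests)
  expect_true(all(gs$planted %in% out$final))
  # false additions controlled at the FDR level
  expect_lte(length(setdiff(out$final, gs$planted)),
             max(1, 0.1 * length(out$final)))
  enr <- hypergeom_enrichment(out$final, gs$term_map, gs$background)
  expect_lt(enr$q[enr$term_id == "planted_term"], 0.05)
  # PSG totals respond to the planted covariate effects
  tot <- attr(gs$psg_table, "totals")
  expect_equal(unname(tot), unname(rowSums(gs$psg_table)))
  expect_true(stats::cor(tot, gs$totals_expected[names(tot)]) > 0.5)
})
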