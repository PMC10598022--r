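test_that("pruning matches the two-tip closed form and stationarity limit", {
  model <- equal_rates_model()
  t2 <- canonical_tree(ape::read.tree(text = "(a:0.07,b:0.08);"))
  ll <- site_log_likelihood(t2, c(a = "A", b = "A"), model)
  paa <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * 0.15)
  expect_equal(ll, log(paa / 20), tolerance = 1e-12)

  t_far <- canonical_tree(ape::read.tree(text = "(a:60,b:60);"))
  ll_far <- site_log_likelihood(t_far, c(a = "A", b = "R"), model)
  expect_equal(ll_far, log(1 / 400), tolerance = 1e-6)

  expect_error(site_log_likelihood(t2, c(a = "-", b = "-")), "all-gap")
})

test_that("pruning equals exhaustive enumeration over internal labelings", {
  model <- equal_rates_model()
  t4 <- random_tree(4, 21)
  t5 <- random_tree(5, 22)
  set.seed(5)
  cols4 <- replicate(3, stats::setNames(sample(amino_acids(), 4, TRUE),
                                        t4$tip.label), simplify = FALSE)
  for (col in cols4) {
    expect_equal(site_log_likelihood(t4, col, model),
                 log(brute_force_likelihood(t4, col, model)),
                 tolerance = 1e-10)
  }
  col5 <- stats::setNames(c("A", "A", "S", "S", "T"), t5$tip.label)
  expect_equal(site_log_likelihood(t5, col5, model),
               log(brute_force_likelihood(t5, col5, model)),
               tolerance = 1e-10)
})

test_that("marginal posteriors equal brute-force Bayes on a 4-tip tree", {
  t4 <- random_tree(4, 31)
  aln <- rbind(c("A", "S"), c("A", "S"), c("R", "T"), c("A", "T"))
  rownames(aln) <- t4$tip.label
  asr <- marginal_ancestral_states(t4, aln)
  for (nd in t4$node.label) {
    for (s in 1:2) {
      post <- brute_force_posterior(t4, aln[, s], nd)
      expect_equal(unname(asr$posterior[nd, s]), max(post), tolerance = 1e-10)
      expect_equal(unname(asr$states[nd, s]), names(which.max(post)))
    }
  }
})

test_that("identical tips give confident no-change reconstructions", {
  tr <- canonical_tree(ape::read.tree(
    text = "((a:0.02,b:0.02):0.03,(c:0.02,d:0.02):0.03);"))
  aln <- matrix("R", 4, 3, dimnames = list(tr$tip.label, NULL))
  asr <- marginal_ancestral_states(tr, aln)
  expect_true(all(asr$states == "R"))
  expect_true(all(asr$posterior > 0.99))
})

test_that("symmetric cherries tie at the root and resolve alphabetically", {
  tr <- canonical_tree(ape::read.tree(
    text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);"))
  aln <- matrix(c("S", "S", "T", "T"), 4, 1, dimnames = list(c("a", "b", "c", "d"), NULL))
  asr <- marginal_ancestral_states(tr, aln)
  root_lab <- tr$node.label[1L]  # ape stores the root's label first
  post_S <- brute_force_posterior(tr, aln[, 1], root_lab)
  expect_equal(unname(post_S["S"]), unname(post_S["T"]), tolerance = 1e-12)
  expect_equal(unname(asr$states[root_lab, 1]), "S")

  fp <- fitch_parsimony_states(tr, aln)
  expect_equal(unname(fp$states[root_lab, 1]), "S")
  aln_same <- matrix("K", 4, 2, dimnames = list(tr$tip.label, NULL))
  fp2 <- fitch_parsimony_states(tr, aln_same)
  expect_true(all(fp2$states == "K"))
})

test_that("parsimony change counts equal the exhaustive minimum", {
  for (seed in 1:4) {
    t6 <- random_tree(6, seed + 50)
    set.seed(seed)
    aln <- matrix(sample(c("A", "S", "T", "R"), 6 * 5, TRUE), 6, 5,
                  dimnames = list(t6$tip.label, NULL))
    fp <- fitch_parsimony_states(t6, aln)
    for (s in 1:5) {
      expect_equal(fp$changes[s], brute_force_parsimony(t6, aln[, s]))
    }
  }
})

test_that("pair substitution counting follows the C/D definitions", {
  tr <- tree3()
  # site patterns: (m, s_a, s_b) with mrca(a, b) the cherry node
  m_lab <- tr$node.label[mrca_node(tr, "a", "b") - ape::Ntip(tr)]
  root_lab <- setdiff(tr$node.label, m_lab)
  states <- structure(list(
    states = matrix("A", 2, 4, dimnames = list(c(m_lab, root_lab), NULL)),
    posterior = matrix(1, 2, 4, dimnames = list(c(m_lab, root_lab), NULL)),
    method = "supplied"), class = "ancestral_states")
  aln <- rbind(a = c("S", "S", "A", "-"),
               b = c("S", "T", "T", "S"),
               c = c("A", "A", "A", "A"))
  cd <- count_pair_substitutions(states, aln, tr, "a", "b")
  # site 1: both changed to S -> C; site 2: changed differently -> D;
  # site 3: single-lineage change -> neither; site 4: gap -> skipped
  expect_equal(cd, c(C = 1L, D = 1L))
  expect_error(count_pair_substitutions(states, aln, tr, "a", "a"),
               "distinct")
  # looser divergence rule counts site 3 as divergent
  cd2 <- count_pair_substitutions(states, aln, tr, "a", "b",
                                  divergent_rule = "any_different")
  expect_equal(cd2[["D"]], 2L)
  # posterior floor removes sites below it
  states$posterior[m_lab, 1] <- 0.4
  cd3 <- count_pair_substitutions(states, aln, tr, "a", "b",
                                  posterior_floor = 0.5)
  expect_equal(cd3[["C"]], 0L)
})

test_that("counts on a simulated gene match the naive per-site oracle", {
  sim <- simulate_tree_and_traits(n_tips = 8, n_origins_plunge = 2,
                                  n_origins_island = 2, seed = 3)
  g <- simulate_alignment_with_convergence(sim$tree, sim$traits,
                                           n_sites = 100, seed = 4)
  truth <- structure(list(states = g$truth$node_states,
                          posterior = matrix(1, nrow(g$truth$node_states),
                                             100,
                                             dimnames = dimnames(g$truth$node_states)),
                          method = "supplied"), class = "ancestral_states")
  pairs <- enumerate_pairs(sim$tree$tip.label)
  for (i in sample(nrow(pairs), 6)) {
    expect_equal(
      count_pair_substitutions(truth, g$alignment, sim$tree,
                               pairs$a[i], pairs$b[i]),
      naive_pair_counts(truth, g$alignment, sim$tree, pairs$a[i], pairs$b[i]))
  }
})

test_that("the pair table aggregates genes additively with focal flags", {
  sim <- simulate_tree_and_traits(n_tips = 8, n_origins_plunge = 2,
                                  n_origins_island = 2, seed = 13)
  ga <- simulate_gene_alignments(sim$tree, sim$traits, n_genes = 3,
                                 n_sites = 60, seed = 14,
                                 reconstruction = "truth")
  pt <- build_pair_table(sim$tree, ga$states, ga$alignments, sim$traits)
  expect_equal(nrow(pt), choose(8, 2))
  expect_true(all(pt$C + pt$D <= 3 * 60))
  # additivity over genes
  i <- which(pt$a == pt$a[1] & pt$b == pt$b[1])[1]
  per_gene <- sapply(names(ga$states), function(g) {
    count_pair_substitutions(ga$states[[g]], ga$alignments[[g]], sim$tree,
                             pt$a[i], pt$b[i])
  })
  expect_equal(pt$C[i], sum(per_gene["C", ]))
  expect_equal(pt$D[i], sum(per_gene["D", ]))
  # per-gene response divides by gene count
  pt2 <- build_pair_table(sim$tree, ga$states, ga$alignments, sim$traits,
                          response = "per_gene")
  expect_equal(pt2$response, pt$C / 3)
  # focal flags need both tips foreground with a non-foreground MRCA state
  plunge <- stats::setNames(sim$traits$plunge, sim$traits$species)
  fit <- fitch_binary_trait(sim$tree, plunge)
  both <- plunge[pt$a] == 1 & plunge[pt$b] == 1
  expect_true(all(pt$plunge_focal[!both] == 0))
  same_clade <- both &
    fit$states[sapply(seq_len(nrow(pt)), function(i)
      mrca_node(sim$tree, pt$a[i], pt$b[i]))] == 1L
  expect_true(all(pt$plunge_focal[same_clade] == 0))
  expect_true(all(pt$plunge_focal[both & !same_clade] == 1))
  # a gene missing one tip is skipped with a warning
  short <- ga$alignments
  short[[2]] <- short[[2]][-1, ]
  expect_warning(
    pt3 <- build_pair_table(sim$tree, ga$states, short, sim$traits),
    "skipping")
  expect_equal(unique(pt3$n_genes), 2L)
})

test_that("ML and parsimony agree on high-posterior states", {
  sim <- simulate_tree_and_traits(n_tips = 8, n_origins_plunge = 2,
                                  n_origins_island = 2, seed = 23)
  agree <- total <- 0
  for (s in 1:3) {
    g <- simulate_alignment_with_convergence(sim$tree, sim$traits,
                                             n_sites = 100, seed = 30 + s)
    ml <- marginal_ancestral_states(sim$tree, g$alignment)
    pars <- fitch_parsimony_states(sim$tree, g$alignment)
    hi <- ml$posterior >= 0.95
    agree <- agree + sum(ml$states[hi] == pars$states[hi])
    total <- total + sum(hi)
  }
  expect_gt(agree / total, 0.95)
})
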