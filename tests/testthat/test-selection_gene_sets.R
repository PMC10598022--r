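test_that("bh_fdr matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent hand implementation of the step-up rule
  set.seed(1)
  p <- stats::runif(50)^2
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_hand <- numeric(m); q_hand[o] <- pmin(q_sorted, 1)
  expect_equal(bh_fdr(p), q_hand)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("confirmation percentage reproduces the 308-of-1426 report", {
  expect_equal(confirmation_percentage(308, 1426), 21.6)
  expect_equal(confirmation_percentage(1, 3), 33.3)
})

test_that("adaptive_convergent_set performs the documented set algebra", {
  mk <- function(test, genes, score, branch = NA_character_) {
    data.frame(gene_id = genes, test_name = test, branch_id = branch,
               score = score, qvalue = NA_real_)
  }
  # toy example: BS & RELAX confirm g1-g3, per-branch gives g2-g4 on two
  # lineages, residue test passes only g3
  genes <- paste0("g", 1:6)
  res <- rbind(
    mk("branch_site", genes, c(1e-5, 1e-5, 1e-5, 0.9, 0.9, 0.9)),
    mk("relax", genes, c(1e-5, 1e-5, 1e-5, 0.9, 0.9, 0.9)),
    mk("branch_adaptive", rep(genes, 2),
       rep(c(0.9, 1e-5, 1e-5, 1e-5, 0.9, 0.9), 2),
       rep(c("sp1", "sp2"), each = 6)),
    mk("residue_convergence", genes, c(0, 0, 0.95, 0.9, 0, 0)))
  out <- adaptive_convergent_set(res)
  expect_equal(out$final, "g3")
  expect_equal(out$sets$confirmed, c("g1", "g2", "g3"))
  expect_equal(out$sets$per_branch, c("g2", "g3", "g4"))
  expect_equal(out$confirmation_pct, 100)
  # single significant lineage is not enough
  out2 <- adaptive_convergent_set(res, min_lineages = 3)
  expect_equal(out2$final, character(0))
  expect_error(adaptive_convergent_set(res[res$test_name != "relax", ]),
               "relax")

  # randomized tables match a brute-force evaluation
  set.seed(4)
  n <- 500
  g <- sprintf("g%03d", 1:n)
  res <- rbind(
    mk("branch_site", g, stats::runif(n)),
    mk("relax", g, stats::runif(n)),
    mk("branch_adaptive", rep(g, 3), stats::runif(3 * n),
       rep(c("s1", "s2", "s3"), each = n)),
    mk("residue_convergence", g, stats::runif(n)))
  out <- adaptive_convergent_set(res)
  q_of <- function(test) {
    d <- res[res$test_name == test, ]
    d$q <- stats::p.adjust(d$score, "BH")
    d
  }
  bs <- q_of("branch_site"); rl <- q_of("relax")
  s1 <- intersect(bs$gene_id[bs$q < 0.05], rl$gene_id[rl$q < 0.05])
  ba <- res[res$test_name == "branch_adaptive", ]
  sig_by_branch <- lapply(split(ba, ba$branch_id), function(d) {
    d$gene_id[stats::p.adjust(d$score, "BH") < 0.05]
  })
  cnt <- table(unlist(lapply(sig_by_branch, unique)))
  s2 <- names(cnt)[cnt >= 2]
  rc <- res[res$test_name == "residue_convergence", ]
  s3 <- rc$gene_id[rc$score >= 0.8]
  expect_equal(out$final, sort(Reduce(intersect, list(s1, s2, s3))))
  expect_equal(out$euler[["branch_site"]], length(bs$gene_id[bs$q < 0.05]))

  # monotone: tightening any threshold never grows the final set
  tighter <- adaptive_convergent_set(res, fdr = 0.01,
                                     residue_posterior = 0.9,
                                     min_lineages = 3)
  expect_true(all(tighter$final %in% out$final))
})

test_that("hypergeometric enrichment is exact", {
  tm <- data.frame(term_id = "t1", gene_id = sprintf("g%02d", 1:5))
  bg <- sprintf("g%02d", 1:20)
  res <- hypergeom_enrichment(sprintf("g%02d", 1:5), tm, bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L)

  # term covering the whole background has p = 1
  tm2 <- data.frame(term_id = "all", gene_id = bg)
  res2 <- hypergeom_enrichment(sprintf("g%02d", 1:5), tm2, bg)
  expect_equal(res2$p, 1)

  # exact tail matches Monte-Carlo within 3 MC standard errors
  set.seed(6)
  for (i in 1:5) {
    N <- sample(30:60, 1); K <- sample(5:15, 1); n <- sample(5:15, 1)
    bg <- sprintf("b%03d", 1:N)
    term_genes <- sample(bg, K)
    draws <- replicate(20000, {
      length(intersect(sample(bg, n), term_genes))
    })
    target <- sample(bg, n)
    k <- length(intersect(target, term_genes))
    if (k == 0) next
    p_mc <- mean(draws >= k)
    p_exact <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-3)
  }
  expect_error(hypergeom_enrichment("nope", tm, bg), "outside background")
})

test_that("psg_counts thresholds q-values into per-species totals", {
  d <- data.frame(gene_id = rep(sprintf("g%02d", 1:10), 2),
                  test_name = "branch_adaptive",
                  branch_id = rep(c("spA", "spB"), each = 10),
                  score = NA_real_,
                  qvalue = c(c(0.01, 0.2, 0.03, 0.6, 0.04, 0.9, 0.01, 0.7,
                               0.2, 0.3),
                             rep(0.5, 10)))
  d$score <- d$qvalue
  M <- psg_counts(d)
  expect_equal(unname(attr(M, "totals")), c(4L, 0L))
  M2 <- psg_counts(d, q_threshold = 1.0)
  expect_equal(unname(attr(M2, "totals")), c(10L, 10L))
  # brute-force filter-count oracle
  brute <- sum(d$qvalue[d$branch_id == "spA"] < 0.05)
  expect_equal(attr(M, "totals")[["spA"]], brute)
})

test_that("PGLS with lambda fixed at zero equals OLS", {
  sim <- simulate_tree_and_traits(n_tips = 12, n_origins_plunge = 3,
                                  n_origins_island = 3, seed = 61)
  gs <- simulate_gene_tests_and_psgs(sim$tree, sim$traits, seed = 62)
  tot <- attr(gs$psg_table, "totals")
  fit0 <- fit_pgls_lambda(tot, sim$traits, sim$tree, lambda = 0)
  d <- sim$traits; d$psg <- tot[d$species]
  ols <- stats::lm(psg ~ plunge + mass + island + mass:island, data = d)
  expect_equal(unname(fit0$coefficients$estimate),
               unname(stats::coef(ols)[c("(Intercept)", "plunge", "mass",
                                         "island", "mass:island")]),
               tolerance = 1e-8)
})

test_that("PGLS coefficients match an nlme::gls oracle at fixed lambda", {
  skip_if_not_installed("nlme")
  sim <- simulate_tree_and_traits(n_tips = 14, n_origins_plunge = 3,
                                  n_origins_island = 3, seed = 63)
  gs <- simulate_gene_tests_and_psgs(sim$tree, sim$traits, seed = 64)
  tot <- attr(gs$psg_table, "totals")
  lam <- 0.55
  fit <- fit_pgls_lambda(tot, sim$traits, sim$tree, lambda = lam)
  d <- sim$traits; d$psg <- tot[d$species]
  rownames(d) <- d$species
  co <- ape::corPagel(lam, sim$tree, fixed = TRUE, form = ~species)
  or <- nlme::gls(psg ~ plunge + mass + island + mass:island, data = d,
                  correlation = co)
  expect_equal(unname(fit$coefficients$estimate),
               unname(stats::coef(or)), tolerance = 1e-6)
})

test_that("lambda is recovered under Brownian motion and on star trees", {
  bm_hat <- sapply(1:25, function(r) {
    tr <- random_tree(50, 600 + r)
    set.seed(700 + r)
    y <- simulate_bm(tr, sigma2 = 4) + 10
    tm <- data.frame(species = tr$tip.label, plunge = 0, island = 0,
                     mass = stats::rnorm(50))
    fit_pgls_lambda(y, tm, tr, psg ~ mass)$lambda
  })
  expect_gte(mean(bm_hat >= 0.8), 0.9)
  # star-tree (iid) data carry no phylogenetic signal, so fitting with the
  # structured tree should drive lambda to the floor
  star_hat <- sapply(1:25, function(r) {
    tr <- random_tree(50, 800 + r)
    set.seed(850 + r)
    y <- stats::setNames(stats::rnorm(50), tr$tip.label)
    tm <- data.frame(species = tr$tip.label, plunge = 0, island = 0,
                     mass = stats::rnorm(50))
    fit_pgls_lambda(y, tm, tr, psg ~ mass)$lambda
  })
  expect_gte(mean(star_hat <= 0.2), 0.9)
})

test_that("stepwise AIC selection is deterministic and hierarchical", {
  sim <- simulate_tree_and_traits(n_tips = 50, n_origins_plunge = 4,
                                  n_origins_island = 5, seed = 71)
  # pure mass effect: selection should keep mass and drop the interaction
  kept_mass <- dropped_int <- 0
  for (r in 1:10) {
    set.seed(900 + r)
    y <- stats::setNames(100 - 15 * sim$traits$mass + stats::rnorm(50, 0, 3),
                         sim$traits$species)
    sel <- stepwise_aic(y, sim$traits, sim$tree)
    terms <- as.character(sel$coefficients$term)
    if ("mass" %in% terms) kept_mass <- kept_mass + 1
    if (!"mass:island" %in% terms) dropped_int <- dropped_int + 1
    # hierarchy: interaction present only with both main effects
    if ("mass:island" %in% terms) {
      expect_true(all(c("mass", "island") %in% terms))
    }
  }
  expect_gte(kept_mass, 9)
  expect_gte(dropped_int, 8)
  # identical input gives identical trace
  set.seed(901)
  y <- stats::setNames(100 - 15 * sim$traits$mass + stats::rnorm(50, 0, 3),
                       sim$traits$species)
  s1 <- stepwise_aic(y, sim$traits, sim$tree)
  s2 <- stepwise_aic(y, sim$traits, sim$tree)
  expect_identical(attr(s1, "trace"), attr(s2, "trace"))
})

test_that("overlap comparison counts intersections and letters groups", {
  # identical PSG rows: one shared letter
  st <- star_tree(9)
  M <- matrix(0L, 9, 40, dimnames = list(st$tip.label, sprintf("g%02d", 1:40)))
  M[, 1:12] <- 1L
  class(M) <- c("psg_table", class(M))
  grp <- enumerate_pairs(st$tip.label)
  grp$group <- rep(c("u", "v"), length.out = nrow(grp))
  res <- overlap_comparison(M, st, grp)
  expect_true(all(res$pairs$overlap == 12))
  expect_equal(res$groups$letter[1], res$groups$letter[2])

  # planted separation: strongly different group means get distinct letters
  sim <- simulate_tree_and_traits(n_tips = 12, n_origins_plunge = 3,
                                  n_origins_island = 3, seed = 81)
  gs <- simulate_gene_tests_and_psgs(sim$tree, sim$traits, seed = 82)
  grp <- default_pair_groups(sim$tree, sim$traits)
  res <- overlap_comparison(gs$psg_table, sim$tree, grp)
  # brute-force overlap oracle
  i <- 5
  brute <- sum(gs$psg_table[grp$a[i], ] == 1 & gs$psg_table[grp$b[i], ] == 1)
  expect_equal(res$pairs$overlap[i], brute)
  lf <- res$groups$letter[res$groups$group == "focal_plunge"]
  lb <- res$groups$letter[res$groups$group == "background"]
  expect_false(any(strsplit(lf, "")[[1]] %in% strsplit(lb, "")[[1]]))

  grp_bad <- grp; grp_bad$group[grp_bad$group == "focal_plunge"] <- "background"
  grp_bad$group[1] <- "focal_plunge"
  expect_error(overlap_comparison(gs$psg_table, sim$tree, grp_bad),
               "fewer than 3")
})
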