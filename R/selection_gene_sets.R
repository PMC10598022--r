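# Combination logic for externally computed selection/convergence tests:
# FDR control, adaptively-convergent gene-set intersection, hypergeometric
# enrichment against a custom background, per-species PSG counts, Pagel's
# lambda PGLS of counts on covariates with stepwise AIC selection, and
# pairwise PSG-overlap comparison between groups of species pairs.

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Confirmation percentage of a filtered gene set
#'
#' Share of genes surviving a confirmation filter, as the percentage
#' `100 * n_confirmed / n_total` rounded to one decimal (e.g. 308 of 1426
#' gives 21.6).
#'
#' @param n_confirmed,n_total Nonnegative counts, `n_total` > 0.
#' @return Numeric percentage, one decimal.
#' @export
confirmation_percentage <- function(n_confirmed, n_total) {
  stopifnot(n_total > 0, n_confirmed >= 0, n_confirmed <= n_total)
  round(100 * n_confirmed / n_total, 1)
}

# q-values for one test's rows: use supplied qvalue column, else BH on score
test_q <- function(d) {
  if (all(!is.na(d$qvalue))) d$qvalue else bh_fdr(d$score)
}

#' Intersect selection tests into the adaptively-convergent gene set
#'
#' Three component sets are built from the registered tests and
#' intersected: set 1 holds genes significant in the branch-site
#' foreground test (q < `fdr`) that are confirmed by the relaxed-selection
#' test (q < `fdr`); set 2 holds genes whose per-branch adaptive test is
#' significant (q < `fdr`) on at least `min_lineages` focal branches;
#' set 3 holds genes with residue-convergence posterior >=
#' `residue_posterior`.  The confirmation percentage is
#' `100 * |set 1| / |branch-site significant|`, one decimal.
#'
#' @param results Gene-test data frame (see [read_gene_test_table()])
#'   covering tests `branch_site`, `relax`, `branch_adaptive`,
#'   `residue_convergence`.
#' @param fdr FDR threshold (default 0.05).
#' @param residue_posterior Residue-convergence posterior threshold
#'   (default 0.8).
#' @param min_lineages Minimum focal lineages for set 2 (default 2).
#' @param focal_branches Branch ids counted as focal for set 2 (default:
#'   all branches present in the per-branch test).
#' @return List: `final` (gene ids), `sets` (the three component sets and
#'   the raw branch-site set), `euler` (all intersection counts),
#'   `confirmation_pct`.
#' @export
adaptive_convergent_set <- function(results, fdr = 0.05,
                                    residue_posterior = 0.8,
                                    min_lineages = 2,
                                    focal_branches = NULL) {
  results <- validate_gene_tests(results)
  need <- c("branch_site", "relax", "branch_adaptive", "residue_convergence")
  missing <- setdiff(need, unique(results$test_name))
  if (length(missing)) stop("missing test(s): ", paste(missing, collapse = ", "))
  by_test <- split(results, results$test_name)
  bs <- by_test$branch_site
  bs_set <- bs$gene_id[test_q(bs) < fdr]
  rl <- by_test$relax
  relax_set <- rl$gene_id[test_q(rl) < fdr]
  set1 <- intersect(bs_set, relax_set)
  ba <- by_test$branch_adaptive
  if (is.null(focal_branches)) focal_branches <- unique(ba$branch_id)
  ba <- ba[ba$branch_id %in% focal_branches, , drop = FALSE]
  ba_sig <- ba[test_q(ba) < fdr, , drop = FALSE]
  lineage_counts <- table(unique(ba_sig[c("gene_id", "branch_id")])$gene_id)
  set2 <- names(lineage_counts)[lineage_counts >= min_lineages]
  rc <- by_test$residue_convergence
  set3 <- rc$gene_id[rc$score >= residue_posterior]
  final <- Reduce(intersect, list(set1, set2, set3))
  euler <- c(
    branch_site = length(bs_set), confirmed = length(set1),
    per_branch_2plus = length(set2), residue = length(set3),
    confirmed_and_branch = length(intersect(set1, set2)),
    confirmed_and_residue = length(intersect(set1, set3)),
    branch_and_residue = length(intersect(set2, set3)),
    final = length(final))
  list(final = sort(final),
       sets = list(branch_site = sort(bs_set), confirmed = sort(set1),
                   per_branch = sort(set2), residue = sort(set3)),
       euler = euler,
       confirmation_pct = if (length(bs_set)) {
         confirmation_percentage(length(set1), length(bs_set))
       } else NA_real_)
}

#' Hypergeometric enrichment of a gene set against a custom background
#'
#' For each term with at least one target gene, computes the exact
#' upper-tail probability \eqn{P(X \ge k)} of drawing `k` term genes in a
#' target of size `n` from a background of size `N` containing `K` term
#' genes, plus fold enrichment and BH q-values over the tested terms.
#'
#' @param target_genes Character vector (subset of `background`).
#' @param term_map Data frame with columns `term_id`, `gene_id`.
#' @param background Character vector of background gene ids.
#' @return Data frame: `term_id`, `k`, `n`, `K`, `N`, `fold`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(target_genes, term_map, background) {
  background <- unique(background)
  target_genes <- unique(target_genes)
  out <- setdiff(target_genes, background)
  if (length(out)) {
    stop("target gene(s) outside background: ", paste(out, collapse = ", "))
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(target_genes)
  res <- lapply(split(term_map$gene_id, term_map$term_id), function(genes) {
    genes <- unique(genes)
    K <- length(genes)
    k <- length(intersect(genes, target_genes))
    if (k == 0L) return(NULL)
    data.frame(k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p = numeric(), q = numeric()))
  }
  d <- do.call(rbind, res[keep])
  d <- cbind(term_id = names(res)[keep], d)
  rownames(d) <- NULL
  d$q <- bh_fdr(d$p)
  d[order(d$p), ]
}

#' Tabulate positively selected genes per species branch
#'
#' Thresholds per-branch adaptive-test q-values and builds the species x
#' gene indicator matrix with per-species totals.
#'
#' @param per_branch_results Gene-test rows of the per-branch adaptive
#'   test (q-values used if present, else BH within branch).
#' @param q_threshold Significance threshold (default 0.05).
#' @return A `psg_table`: binary matrix (branches x genes) with totals in
#'   `attr(, "totals")`.
#' @export
psg_counts <- function(per_branch_results, q_threshold = 0.05) {
  d <- per_branch_results[per_branch_results$test_name %in% per_branch_tests(), ,
                          drop = FALSE]
  branches <- sort(unique(d$branch_id))
  genes <- sort(unique(d$gene_id))
  M <- matrix(0L, length(branches), length(genes),
              dimnames = list(branches, genes))
  for (br in branches) {
    rows <- d[d$branch_id == br, , drop = FALSE]
    q <- test_q(rows)
    sig <- unique(rows$gene_id[q < q_threshold])
    M[br, sig] <- 1L
  }
  attr(M, "totals") <- rowSums(M)
  class(M) <- c("psg_table", class(M))
  M
}

# GLS machinery with lambda-scaled phylogenetic covariance
lambda_cov <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

gls_fit <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) stop("covariance not PD"))
  Ty <- forwardsolve(t(ch), y)
  TX <- forwardsolve(t(ch), X)
  qr_x <- qr(TX)
  if (qr_x$rank < ncol(X)) stop("non-identifiable design")
  beta <- drop(solve(crossprod(TX), crossprod(TX, Ty)))
  r <- Ty - TX %*% beta
  n <- length(y)
  sigma2 <- sum(r^2) / n                  # ML estimate
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
  covb <- sigma2 * n / (n - ncol(X)) * solve(crossprod(TX))
  T1 <- forwardsolve(t(ch), matrix(1, n, 1))
  mu0 <- drop(solve(crossprod(T1), crossprod(T1, Ty)))
  tss <- sum((Ty - T1 * mu0)^2)
  list(beta = beta, sigma2 = sigma2, logLik = ll, covb = covb,
       rss = sum(r^2), tss = tss)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `model_formula` by GLS under a lambda-scaled phylogenetic
#' covariance (off-diagonal entries multiplied by lambda), with lambda
#' estimated by profile maximum likelihood on [0, 1]
#' ([stats::optimize()], tolerance 1e-6).
#'
#' @param totals Named numeric response (e.g. PSG totals per species).
#' @param trait_map Trait data frame with `species`, `plunge`, `island`,
#'   `mass`.
#' @param tree `phylo` covering all species.
#' @param model_formula Model formula in terms of `psg`, `plunge`, `mass`,
#'   `island` (default `psg ~ plunge + mass + island + mass:island`).
#' @param lambda Fix lambda instead of estimating it (optional).
#' @return A `pgls_fit`: coefficient table (estimate, se, t, p), `lambda`,
#'   `sigma2`, `adj_r2`, `AIC`, `logLik`, `formula`, `n`.
#' @export
fit_pgls_lambda <- function(totals, trait_map, tree,
                            model_formula = psg ~ plunge + mass + island +
                              mass:island,
                            lambda = NULL) {
  trait_map <- as.data.frame(trait_map)
  sp <- intersect(tree$tip.label, names(totals))
  if (length(sp) < 8L) stop("need totals for at least 8 species on the tree")
  d <- trait_map[match(sp, trait_map$species), , drop = FALSE]
  d$psg <- as.numeric(totals[sp])
  X <- stats::model.matrix(stats::delete.response(stats::terms(model_formula)),
                           data = d)
  y <- d$psg
  C <- phylo_covariance(tree, sp)
  profile_ll <- function(lam) gls_fit(y, X, lambda_cov(C, lam))$logLik
  lam_hat <- if (!is.null(lambda)) lambda else {
    opt <- stats::optimize(profile_ll, c(0, 1), maximum = TRUE, tol = 1e-6)
    # compare against the boundary values, which optimize can miss
    cand <- c(opt$maximum, 0, 1)
    cand[which.max(vapply(cand, profile_ll, numeric(1)))]
  }
  fit <- gls_fit(y, X, lambda_cov(C, lam_hat))
  n <- length(y); p <- ncol(X)
  se <- sqrt(diag(fit$covb))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), n - p)
  k <- p + 1 + if (is.null(lambda)) 1 else 0  # coefs + sigma2 (+ lambda)
  r2 <- 1 - fit$rss / fit$tss
  out <- list(coefficients = data.frame(term = colnames(X),
                                        estimate = fit$beta, se = se,
                                        t = tval, p = pval, row.names = NULL),
              lambda = lam_hat, sigma2 = fit$sigma2,
              adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
              AIC = -2 * fit$logLik + 2 * k, logLik = fit$logLik,
              formula = model_formula, n = n)
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.3f, sigma2 = %.3g, adj R2 = %.3f, AIC = %.2f)\n",
              x$lambda, x$sigma2, x$adj_r2, x$AIC))
  cf <- x$coefficients
  cf[-1L] <- lapply(cf[-1L], signif, 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

formula_terms <- function(f) attr(stats::terms(f), "term.labels")

term_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

#' Bidirectional AIC-based model selection for the PSG PGLS
#'
#' Greedy add/drop steps over the terms of `full_formula`, keeping the
#' hierarchy (an interaction is only present with both main effects);
#' stops when no single move lowers the AIC.  Deterministic for a given
#' input.
#'
#' @param totals,trait_map,tree As in [fit_pgls_lambda()].
#' @param full_formula The full model (default the four-term PSG model).
#' @return The selected `pgls_fit` (with the search trace in
#'   `attr(, "trace")`).
#' @export
stepwise_aic <- function(totals, trait_map, tree,
                         full_formula = psg ~ plunge + mass + island +
                           mass:island) {
  universe <- formula_terms(full_formula)
  current <- universe
  refit <- function(terms) {
    f <- if (length(terms) == 0L) psg ~ 1 else
      stats::reformulate(terms, response = "psg")
    fit_pgls_lambda(totals, trait_map, tree, f)
  }
  fit <- refit(current)
  trace <- data.frame(move = "start", term = NA_character_, AIC = fit$AIC)
  repeat {
    cand <- list()
    for (tm in current) {  # drops keeping hierarchy
      rest <- setdiff(current, tm)
      has_child <- any(vapply(rest, function(o) {
        length(term_parents(o)) > 1L && tm %in% term_parents(o)
      }, logical(1)))
      if (!has_child) cand[[length(cand) + 1L]] <- list(move = "drop", term = tm,
                                                        terms = rest)
    }
    for (tm in setdiff(universe, current)) {  # adds keeping hierarchy
      if (all(term_parents(tm) %in% c(current, tm))) {
        cand[[length(cand) + 1L]] <- list(move = "add", term = tm,
                                          terms = c(current, tm))
      }
    }
    if (length(cand) == 0L) break
    fits <- lapply(cand, function(cc) refit(cc$terms))
    aics <- vapply(fits, `[[`, numeric(1), "AIC")
    best <- which.min(aics)
    if (aics[best] >= fit$AIC - 1e-8) break
    fit <- fits[[best]]
    current <- cand[[best]]$terms
    trace <- rbind(trace, data.frame(move = cand[[best]]$move,
                                     term = cand[[best]]$term,
                                     AIC = fit$AIC))
  }
  attr(fit, "trace") <- trace
  fit
}

#' Default grouping of species pairs for overlap comparisons
#'
#' Labels each pair `focal_plunge` (both tips plunge-dive with independent
#' origins), else `focal_island` (both insular, independent origins), else
#' `background`.
#'
#' @param tree Species `phylo`.
#' @param trait_map Trait data frame.
#' @return Data frame `a`, `b`, `group` over all unordered pairs.
#' @export
default_pair_groups <- function(tree, trait_map) {
  trait_map <- validate_trait_map(as.data.frame(trait_map), tree)
  plunge <- stats::setNames(trait_map$plunge, trait_map$species)
  island <- stats::setNames(trait_map$island, trait_map$species)
  fit_p <- fitch_binary_trait(tree, plunge)
  fit_i <- fitch_binary_trait(tree, island)
  pairs <- enumerate_pairs(tree$tip.label)
  grp <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mn <- mrca_node(tree, pairs$a[i], pairs$b[i])
    if (plunge[pairs$a[i]] == 1 && plunge[pairs$b[i]] == 1 &&
        fit_p$states[mn] == 0L) {
      grp[i] <- "focal_plunge"
    } else if (island[pairs$a[i]] == 1 && island[pairs$b[i]] == 1 &&
               fit_i$states[mn] == 0L) {
      grp[i] <- "focal_island"
    } else {
      grp[i] <- "background"
    }
  }
  cbind(pairs, group = grp)
}

#' Compare PSG overlap between groups of species pairs
#'
#' The response for each pair is the number of genes positively selected
#' in both species.  A mixed model with group fixed effects and random
#' intercepts for species a, species b and the pair's MRCA node (with
#' phylogenetic covariance) is fitted by REML; groups are compared by
#' pairwise Wald contrasts at `alpha`, summarized as a compact letter
#' display (groups sharing a letter are not significantly different),
#' letters assigned greedily by descending mean.
#'
#' @param psg_table A `psg_table` whose row names are species.
#' @param tree Species `phylo` with canonical node labels.
#' @param groups Data frame `a`, `b`, `group` covering the pairs to use
#'   (e.g. from [default_pair_groups()]); every group needs >= 3 pairs.
#' @param alpha Significance level for contrasts (default 0.05).
#' @return List: `groups` (group, n, mean, emmean, letter), `contrasts`
#'   (pairwise estimate, se, p), `pairs` (per-pair overlaps), `fit`.
#' @export
overlap_comparison <- function(psg_table, tree, groups, alpha = 0.05) {
  sp <- rownames(psg_table)
  groups <- groups[groups$a %in% sp & groups$b %in% sp, , drop = FALSE]
  tab <- table(groups$group)
  if (any(tab < 3L)) {
    stop("group(s) with fewer than 3 pairs: ",
         paste(names(which(tab < 3L)), collapse = ", "))
  }
  ov <- vapply(seq_len(nrow(groups)), function(i) {
    sum(psg_table[groups$a[i], ] & psg_table[groups$b[i], ])
  }, numeric(1))
  n <- length(ov)
  mrca_id <- vapply(seq_len(nrow(groups)), function(i) {
    tree$node.label[mrca_node(tree, groups$a[i], groups$b[i]) - ape::Ntip(tree)]
  }, character(1))
  g <- factor(groups$group)
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  lev <- sort(unique(c(groups$a, groups$b)))
  Za <- indicator(factor(groups$a, levels = lev))
  Zb <- indicator(factor(groups$b, levels = lev))
  mlev <- sort(unique(mrca_id))
  Zm <- indicator(factor(mrca_id, levels = mlev))
  A <- normalize_node_cov(phylo_covariance(tree, mlev)) +
    diag(1e-8, length(mlev))
  kernels <- list(lineage_a = tcrossprod(Za), lineage_b = tcrossprod(Zb),
                  mrca = Zm %*% A %*% t(Zm))
  fit <- reml_pair_lmm(ov, X, kernels, n)
  means <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  ses <- stats::setNames(fit$fixed$se, fit$fixed$term)
  # covariance of group means for contrasts
  v <- fit$varcomp
  V <- diag(v["residual"], n)
  for (i in seq_along(kernels)) V <- V + v[i] * kernels[[i]]
  ch <- chol(V)
  TX <- forwardsolve(t(ch), X)
  covb <- solve(crossprod(TX))
  df <- n - ncol(X)
  cmb <- utils::combn(levels(g), 2L)
  contrasts <- data.frame(g1 = cmb[1L, ], g2 = cmb[2L, ])
  contrasts$estimate <- means[contrasts$g1] - means[contrasts$g2]
  contrasts$se <- vapply(seq_len(ncol(cmb)), function(i) {
    c1 <- match(cmb[1L, i], levels(g)); c2 <- match(cmb[2L, i], levels(g))
    sqrt(covb[c1, c1] + covb[c2, c2] - 2 * covb[c1, c2])
  }, numeric(1))
  contrasts$p <- 2 * stats::pt(-abs(contrasts$estimate / contrasts$se), df)
  contrasts$p[!is.finite(contrasts$p)] <- 1  # 0/0 contrasts: no difference
  sig <- function(g1, g2) {
    row <- (contrasts$g1 == g1 & contrasts$g2 == g2) |
      (contrasts$g1 == g2 & contrasts$g2 == g1)
    contrasts$p[row] < alpha
  }
  ord <- names(sort(means, decreasing = TRUE))
  letter_sets <- list()
  for (grp in ord) {  # greedy insert
    placed <- FALSE
    for (li in seq_along(letter_sets)) {
      if (!any(vapply(letter_sets[[li]], function(o) sig(grp, o), logical(1)))) {
        letter_sets[[li]] <- c(letter_sets[[li]], grp)
        placed <- TRUE
      }
    }
    if (!placed) letter_sets[[length(letter_sets) + 1L]] <- grp
  }
  letters_of <- vapply(levels(g), function(grp) {
    paste(letters[which(vapply(letter_sets, function(s) grp %in% s,
                               logical(1)))], collapse = "")
  }, character(1))
  group_summary <- data.frame(group = levels(g),
                              n = as.integer(tab[levels(g)]),
                              mean = vapply(levels(g), function(grp) {
                                mean(ov[g == grp])
                              }, numeric(1)),
                              emmean = means[levels(g)],
                              letter = letters_of, row.names = NULL)
  list(groups = group_summary, contrasts = contrasts,
       pairs = cbind(groups, overlap = ov), fit = fit)
}
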