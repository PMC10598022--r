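# Multivariate comparison of effective-population-size trajectory shapes
# between groups: species' log-Ne curves are evaluated on a shared
# log-spaced time grid and regressed on a group indicator under a
# phylogenetic transform, with significance from residual-randomization
# permutation (RRPP).

#' Evaluate trajectories on a common log-spaced time grid
#'
#' The grid holds `n_points` log-spaced times inside the intersection of
#' all species' supports; each trajectory is evaluated as a
#' right-continuous step function and natural-log-transformed.
#'
#' @param trajectories List of [ne_trajectory()] objects (>= 2).
#' @param n_points Grid size (default 64).
#' @return A `curve_matrix`: species x grid matrix of log-Ne with the grid
#'   in `attr(, "grid")`.
#' @export
common_grid <- function(trajectories, n_points = 64) {
  if (length(trajectories) < 2L) stop("need at least 2 trajectories")
  lo <- max(vapply(trajectories, function(x) x$times[1L], numeric(1)))
  hi <- min(vapply(trajectories, function(x) max(x$times), numeric(1)))
  if (hi <= lo) {
    spans <- vapply(trajectories, function(x) {
      sprintf("%s [%.3g, %.3g]", x$species_label, x$times[1L], max(x$times))
    }, character(1))
    stop("no overlapping time support across species: ",
         paste(spans, collapse = "; "))
  }
  # log-spaced grid; shift if the support starts at 0
  eps <- if (lo > 0) 0 else (hi - lo) * 1e-6
  grid <- exp(seq(log(lo + eps), log(hi), length.out = n_points))
  grid <- pmin(pmax(grid, lo + eps), hi)   # guard endpoint rounding
  M <- t(vapply(trajectories, function(x) log(eval_trajectory(x, grid)),
                numeric(n_points)))
  rownames(M) <- vapply(trajectories, `[[`, character(1), "species_label")
  attr(M, "grid") <- grid
  class(M) <- c("curve_matrix", class(M))
  M
}

# symmetric inverse square root with eigenvalue floor
inv_sqrt <- function(C, floor_frac = 1e-12) {
  ev <- eigen(C, symmetric = TRUE)
  vals <- ev$values
  fl <- floor_frac * max(vals)
  if (max(vals) <= 0) stop("singular covariance matrix")
  vals <- pmax(vals, fl)
  ev$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(ev$vectors)
}

#' Distance-based phylogenetic regression of curve shape on a grouping
#'
#' Premultiplies the curve matrix and design by the symmetric inverse
#' square root of the tip phylogenetic covariance, fits the multivariate
#' linear model of transformed curves on the transformed group indicator,
#' and assesses the effect by residual randomization: reduced-model
#' (intercept-only) residual rows are permuted `n_perm` times and
#' \eqn{P_{rand} = (1 + \#\{F_{perm} \ge F_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param curves A `curve_matrix` from [common_grid()] (or any species x
#'   variable matrix with row names).
#' @param group_labels Named vector (or vector aligned with rows) giving
#'   each species' group; >= 2 members per group.
#' @param tree `phylo` covering all species; pass `NULL` for the
#'   non-phylogenetic version (identity covariance).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed; results are reproducible under it.
#' @return An `rrpp_result` list: `SS_effect`, `SS_resid`, `df_effect`,
#'   `df_resid`, `F`, `n_perm`, `P_rand`.
#' @export
dpgls_rrpp <- function(curves, group_labels, tree, n_perm = 999,
                       seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  Y <- unclass(curves)
  attr(Y, "grid") <- NULL
  sp <- rownames(Y)
  if (!is.null(names(group_labels))) group_labels <- group_labels[sp]
  g <- factor(group_labels)
  if (anyNA(g) || length(g) != nrow(Y)) stop("labels must cover all rows")
  if (any(table(g) < 2L)) {
    stop("single-member group: ", paste(names(which(table(g) < 2L)),
                                        collapse = ", "))
  }
  n <- nrow(Y)
  Ti <- if (is.null(tree)) diag(n) else {
    C <- phylo_covariance(tree, sp)
    inv_sqrt(C)
  }
  X <- stats::model.matrix(~ g)
  Yt <- Ti %*% Y
  Xt <- Ti %*% X
  X0 <- Ti %*% matrix(1, n, 1)
  hat <- function(M) M %*% solve(crossprod(M), t(M))
  Hf <- hat(Xt); H0 <- hat(X0)
  df_effect <- qr(Xt)$rank - qr(X0)$rank
  df_resid <- n - qr(Xt)$rank
  R0 <- Yt - H0 %*% Yt          # reduced-model residuals
  fit0 <- H0 %*% Yt
  Fstat <- function(Ymat) {
    ss_eff <- sum((Hf %*% Ymat - H0 %*% Ymat)^2)
    ss_res <- sum((Ymat - Hf %*% Ymat)^2)
    c(ss_eff, ss_res,
      if (ss_res == 0) ifelse(ss_eff == 0, 0, Inf)
      else (ss_eff / df_effect) / (ss_res / df_resid))
  }
  obs <- Fstat(Yt)
  perm_F <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Fstat(fit0 + R0[sample.int(n), , drop = FALSE])[3L]
  }, numeric(1)))
  p <- (1 + sum(perm_F >= obs[3L])) / (n_perm + 1)
  structure(list(SS_effect = obs[1L], SS_resid = obs[2L],
                 df_effect = df_effect, df_resid = df_resid, F = obs[3L],
                 n_perm = n_perm, P_rand = p, perm_F = perm_F),
            class = "rrpp_result")
}

#' @export
print.rrpp_result <- function(x, ...) {
  cat(sprintf(
    "RRPP shape test: SS_effect = %.4g, F(%d, %d) = %.4g, P_rand = %.4g (%d perms)\n",
    x$SS_effect, x$df_effect, x$df_resid, x$F, x$P_rand, x$n_perm))
  invisible(x)
}
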