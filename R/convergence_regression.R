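# Genome-wide convergence model: convergent substitutions per pair
# regressed on divergent substitutions, divergence time, plunge-diving,
# insularity and the divergent-by-time interaction, with paired-lineage
# random effects and an MRCA random effect whose covariance follows the
# phylogeny.  Default estimation is REML with directly profiled variance
# components; a conjugate Gibbs sampler mirrors the Bayesian protocol
# (1e6 iterations, first 25% burn-in, posterior means and credible
# intervals, pMCMC).

#' Randomize which lineage of each pair takes role a vs role b
#'
#' Each record's two lineages are assigned to roles by a fair coin so that
#' every lineage appears roughly equally often in each role across the
#' table.  Only the `a`/`b` labels swap; counts and flags are symmetric.
#'
#' @param pair_records Pair table from [build_pair_table()].
#' @param seed Optional integer seed (fixed seed gives identical output).
#' @return The table with roles shuffled.
#' @export
shuffle_pair_roles <- function(pair_records, seed = NULL) {
  if (nrow(pair_records) == 0L) stop("empty pair table")
  with_seed(seed, {
    flip <- stats::runif(nrow(pair_records)) < 0.5
    tmp <- pair_records$a[flip]
    pair_records$a[flip] <- pair_records$b[flip]
    pair_records$b[flip] <- tmp
    pair_records
  })
}

# scale a node covariance to unit mean diagonal; a depth-zero matrix
# (every MRCA at the root) carries no structure and becomes the identity
normalize_node_cov <- function(A) {
  md <- mean(diag(A))
  if (!is.finite(md) || md <= 0) diag(nrow(A)) else A / md
}

pair_design <- function(pair_records, transform = "identity") {
  y <- pair_records$response
  if (transform == "log1p") y <- log1p(y)
  X <- cbind(`(Intercept)` = 1,
             divergent = pair_records$D,
             time = pair_records$divergence_time,
             plunge = pair_records$plunge_focal,
             island = pair_records$island_focal,
             divergent_x_time = pair_records$D * pair_records$divergence_time)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  list(y = y, X = X)
}

# indicator matrix mapping rows to factor levels
indicator <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Fit the phylogenetic linear mixed model of pairwise convergence
#'
#' Gaussian response with fixed effects `[1, D, time, plunge, island,
#' D x time]` and random intercepts for lineage role a, lineage role b and
#' the pair's MRCA node, the latter with covariance proportional to the
#' phylogenetic covariance of the MRCA nodes (normalized to unit mean
#' diagonal).  `method = "reml"` (default) profiles the four variance
#' components by restricted maximum likelihood; `method = "mcmc"` runs a
#' conjugate Gibbs sampler with weakly-informative inverse-gamma variance
#' priors and reports posterior means, 95% credible intervals and pMCMC
#' (two-sided tail probability).
#'
#' @param pair_records Pair table from [build_pair_table()] (>= 20 rows).
#' @param tree Species `phylo` with canonical node labels covering all
#'   lineages and MRCA ids.
#' @param method `"reml"` or `"mcmc"`.
#' @param transform `"identity"` (default) or `"log1p"` on the response.
#' @param include_mrca Keep the MRCA random effect (default TRUE).
#' @param iterations,burnin_frac,thin Gibbs sampler controls (defaults
#'   1e6, 0.25, 10; ignored for REML).
#' @param seed Seed for the sampler.
#' @param signal_scale `"gaussian"` (default) or `"latent"`, which adds
#'   pi^2/3 to the phylogenetic-signal denominator.
#' @param varcomp_fixed Optional numeric vector fixing the variance
#'   components (lineage a, lineage b, MRCA if included, residual) instead
#'   of estimating them; REML only.
#' @return An object of class `pair_lmm`: list with `fixed` (estimate,
#'   lower, upper, se, p per term), `varcomp`, `signal`, `eta2_plunge`,
#'   `method`, `logLik` (REML) and `n`.
#' @export
fit_pair_lmm <- function(pair_records, tree, method = c("reml", "mcmc"),
                         transform = c("identity", "log1p"),
                         include_mrca = TRUE, iterations = 1e6,
                         burnin_frac = 0.25, thin = 10, seed = NULL,
                         signal_scale = c("gaussian", "latent"),
                         varcomp_fixed = NULL) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  signal_scale <- match.arg(signal_scale)
  if (nrow(pair_records) < 20L) stop("need at least 20 pair records")
  des <- pair_design(pair_records, transform)
  y <- des$y; X <- des$X
  n <- length(y)
  lin_levels <- sort(unique(c(pair_records$a, pair_records$b)))
  Za <- indicator(factor(pair_records$a, levels = lin_levels))
  Zb <- indicator(factor(pair_records$b, levels = lin_levels))
  mrca_levels <- sort(unique(pair_records$mrca_id))
  Zm <- indicator(factor(pair_records$mrca_id, levels = mrca_levels))
  A <- normalize_node_cov(phylo_covariance(tree, mrca_levels))
  evA <- eigen(A, symmetric = TRUE)
  if (min(evA$values) < -1e-8 * max(evA$values)) {
    stop("MRCA covariance is not positive semidefinite")
  }
  A <- A + diag(1e-8 * max(evA$values), nrow(A))  # ridge for invertibility
  Ka <- tcrossprod(Za); Kb <- tcrossprod(Zb); Km <- Zm %*% A %*% t(Zm)
  kernels <- list(lineage_a = Ka, lineage_b = Kb)
  if (include_mrca) kernels$mrca <- Km
  fit <- if (method == "reml") {
    reml_pair_lmm(y, X, kernels, n, varcomp_fixed)
  } else {
    gibbs_pair_lmm(y, X, Za, Zb, Zm, A, include_mrca, iterations,
                   burnin_frac, thin, seed)
  }
  vc <- fit$varcomp
  denom <- sum(vc) + if (signal_scale == "latent") pi^2 / 3 else 0
  fit$signal <- if (include_mrca) unname(vc["mrca"] / denom) else NA_real_
  fit$eta2_plunge <- effect_size_eta2(pair_records, transform = transform)
  fit$method <- if (method == "reml") "REML" else "Bayesian"
  fit$n <- n
  class(fit) <- "pair_lmm"
  fit
}

reml_pair_lmm <- function(y, X, kernels, n, varcomp_fixed = NULL) {
  p <- ncol(X)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8  # degenerate constant response
  nk <- length(kernels)
  neg2reml <- function(logv) {
    v <- exp(logv)
    V <- diag(v[nk + 1L], n)
    for (i in seq_len(nk)) V <- V + v[i] * kernels[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(ViX, X)
    XtViy <- crossprod(ViX, y)
    beta <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    quad <- sum(y * Viy) - sum(XtViy * beta)
    val <- 2 * sum(log(diag(ch))) + determinant(XtViX)$modulus + quad
    if (!is.finite(val)) 1e10 else val
  }
  if (is.null(varcomp_fixed)) {
    init <- log(c(rep(vy / (2 * nk), nk), vy / 2))
    opt <- stats::optim(init, neg2reml, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    v <- exp(opt$par)
    obj <- opt$value
    converged <- opt$convergence == 0
  } else {
    stopifnot(length(varcomp_fixed) == nk + 1L)
    v <- pmax(varcomp_fixed, 0)
    obj <- neg2reml(log(pmax(v, 1e-300)))
    converged <- TRUE
  }
  V <- diag(v[nk + 1L], n)
  for (i in seq_len(nk)) V <- V + v[i] * kernels[[i]]
  ch <- chol(V)
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(ViX, X)
  beta <- drop(solve(XtViX, crossprod(ViX, y)))
  se <- sqrt(diag(solve(XtViX)))
  df <- n - p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  ci <- stats::qt(0.975, df) * se
  fixed <- data.frame(term = colnames(X), estimate = beta,
                      lower = beta - ci, upper = beta + ci, se = se,
                      p = pval, row.names = NULL)
  varcomp <- stats::setNames(v, c(names(kernels), "residual"))
  list(fixed = fixed, varcomp = varcomp, logLik = -obj / 2,
       converged = converged)
}

gibbs_pair_lmm <- function(y, X, Za, Zb, Zm, A, include_mrca, iterations,
                           burnin_frac, thin, seed) {
  n <- length(y); p <- ncol(X)
  qa <- ncol(Za); qm <- ncol(Zm)
  Ainv <- solve(A)
  XtX <- crossprod(X)
  XtX_chol <- chol(XtX)
  na_count <- colSums(Za); nb_count <- colSums(Zb)
  DtD <- crossprod(Zm)  # diagonal
  dm <- diag(DtD)
  a0 <- b0 <- 0.001  # weakly-informative inverse-gamma
  keep_iters <- floor((iterations * (1 - burnin_frac)) / thin)
  betas <- matrix(NA_real_, keep_iters, p, dimnames = list(NULL, colnames(X)))
  vcs <- matrix(NA_real_, keep_iters, 4L,
                dimnames = list(NULL, c("lineage_a", "lineage_b", "mrca",
                                        "residual")))
  with_seed(seed, {
    beta <- drop(solve(XtX, crossprod(X, y)))
    ua <- numeric(qa); ub <- numeric(qa); um <- numeric(qm)
    sa <- sb <- sm <- se <- stats::var(y) / 4
    kept <- 0L
    ia <- max.col(Za); ib <- max.col(Zb); im <- max.col(Zm)
    sum_by <- function(r, idx, q) {
      out <- numeric(q)
      tmp <- rowsum(r, idx)
      out[as.integer(rownames(tmp))] <- tmp[, 1L]
      out
    }
    for (it in seq_len(iterations)) {
      # beta | rest
      r <- y - ua[ia] - ub[ib] - if (include_mrca) um[im] else 0
      mu <- solve(XtX, crossprod(X, r))
      beta <- drop(mu + backsolve(XtX_chol, stats::rnorm(p)) * sqrt(se))
      fitb <- drop(X %*% beta)
      # ua | rest (diagonal precision)
      r <- y - fitb - ub[ib] - if (include_mrca) um[im] else 0
      prec <- na_count / se + 1 / sa
      mua <- sum_by(r, ia, qa) / se / prec
      ua <- mua + stats::rnorm(qa) / sqrt(prec)
      # ub | rest
      r <- y - fitb - ua[ia] - if (include_mrca) um[im] else 0
      prec <- nb_count / se + 1 / sb
      mub <- sum_by(r, ib, qa) / se / prec
      ub <- mub + stats::rnorm(qa) / sqrt(prec)
      if (include_mrca) {
        # um | rest: precision DtD/se + Ainv/sm
        r <- y - fitb - ua[ia] - ub[ib]
        Prec <- diag(dm / se, qm) + Ainv / sm
        chP <- chol(Prec)
        rhs <- sum_by(r, im, qm) / se
        mum <- backsolve(chP, forwardsolve(t(chP), rhs))
        um <- drop(mum + backsolve(chP, stats::rnorm(qm)))
      }
      # variances
      sa <- 1 / stats::rgamma(1, a0 + qa / 2, b0 + sum(ua^2) / 2)
      sb <- 1 / stats::rgamma(1, a0 + qa / 2, b0 + sum(ub^2) / 2)
      if (include_mrca) {
        sm <- 1 / stats::rgamma(1, a0 + qm / 2,
                                b0 + drop(crossprod(um, Ainv %*% um)) / 2)
      }
      e <- y - fitb - ua[ia] - ub[ib] - if (include_mrca) um[im] else 0
      se <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
      if (it > iterations * burnin_frac && (it %% thin == 0L) &&
          kept < keep_iters) {
        kept <- kept + 1L
        betas[kept, ] <- beta
        vcs[kept, ] <- c(sa, sb, if (include_mrca) sm else 0, se)
      }
    }
    betas <- betas[seq_len(kept), , drop = FALSE]
    vcs <- vcs[seq_len(kept), , drop = FALSE]
    est <- colMeans(betas)
    qs <- apply(betas, 2L, stats::quantile, c(0.025, 0.975))
    pmcmc <- apply(betas, 2L, function(b) {
      max(2 * min(mean(b > 0), mean(b < 0)), 1 / length(b))
    })
    fixed <- data.frame(term = colnames(X), estimate = est,
                        lower = qs[1L, ], upper = qs[2L, ],
                        se = apply(betas, 2L, stats::sd), p = pmcmc,
                        row.names = NULL)
    varcomp <- colMeans(vcs)
    if (!include_mrca) varcomp <- varcomp[names(varcomp) != "mrca"]
    list(fixed = fixed, varcomp = varcomp, logLik = NA_real_,
         converged = TRUE, samples = list(beta = betas, varcomp = vcs))
  })
}

#' @export
print.pair_lmm <- function(x, ...) {
  cat(sprintf("Phylogenetic pair mixed model (%s), n = %d pairs\n",
              x$method, x$n))
  fx <- x$fixed
  fx[-1L] <- lapply(fx[-1L], signif, 3)
  print(fx, row.names = FALSE)
  cat("Variance components:",
      paste(sprintf("%s = %.3g", names(x$varcomp), x$varcomp),
            collapse = ", "), "\n")
  cat(sprintf("Phylogenetic signal = %.3f; eta^2(plunge) = %.3f\n",
              x$signal, x$eta2_plunge))
  invisible(x)
}

#' Ordinary-least-squares effect size of plunge-diving
#'
#' eta^2 from a sequential (type I) ANOVA of the pair model with the
#' plunge term entered after divergent count, time and island, and before
#' the divergent-by-time interaction: SS(plunge) / SS(total).
#'
#' @param pair_records Pair table.
#' @param transform `"identity"` or `"log1p"` on the response.
#' @return eta-squared in [0, 1].
#' @export
effect_size_eta2 <- function(pair_records, transform = "identity") {
  y <- pair_records$response
  if (transform == "log1p") y <- log1p(y)
  d <- data.frame(y = y, D = pair_records$D,
                  time = pair_records$divergence_time,
                  plunge = pair_records$plunge_focal,
                  island = pair_records$island_focal)
  if (stats::var(y) == 0) stop("zero total sum of squares")
  fit <- stats::lm(y ~ D + time + island + plunge + D:time, data = d)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  unname(ss[rownames(an) == "plunge"] / sum(ss))
}
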