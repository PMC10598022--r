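---
title: "Quantifying genome-wide convergence on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-wide convergence on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconverge)
```

## The scientific problem

When a phenotype evolves repeatedly on a phylogeny — the motivating system
is plunge-diving foraging and island colonization in kingfishers — the
question is whether the repeated phenotype left a repeated molecular
footprint.  `phyloconverge` implements the full inferential chain for that
question on amino-acid data:

1. reconstruct ancestral protein states on a time-calibrated species tree,
2. count, for every pair of species, sites where both lineages
   independently reached the *same* amino acid that differs from their
   most recent common ancestor (convergent substitutions, `C`) and sites
   where both changed but to *different* residues (divergent
   substitutions, `D`),
3. ask, in a phylogenetic mixed model, whether pairs that independently
   evolved the focal phenotype carry more convergence than the `C`-vs-`D`
   baseline predicts,
4. compare effective-population-size (Ne) trajectory shapes between
   species groups,
5. intersect positive-selection test outputs into an adaptively-convergent
   gene set with enrichment statistics, model per-species counts of
   positively selected genes (PSGs) by PGLS, and
6. scan for convergent rate shifts with permulation null distributions.

A lineage is always the *whole path* from the pair's MRCA to a tip, not
the terminal branch: a substitution anywhere along that path counts for
the pair.  Counting therefore compares observed tip states directly
against the reconstructed MRCA state.

## Ancestral states and the substitution model

Marginal ancestral reconstruction uses Felsenstein pruning under an
equal-rates 20-state amino-acid model with uniform stationary frequencies
and unit-rate normalized branch lengths, so
$P_{ii}(t) = \tfrac{1}{20} + \tfrac{19}{20}e^{-\tfrac{20}{19}t}$.
This is a deliberate simplification: codon-model machinery (under which
such reconstructions are often produced upstream) is out of scope here,
and the package equally accepts externally supplied states
(`read_ancestral_states()`) or Fitch parsimony
(`fitch_parsimony_states()`) as drop-in reconstructors.  The pruning
engine is validated in the test suite against exhaustive enumeration over
all internal labelings on small trees (agreement to $10^{-10}$ in log
likelihood), and the marginal posteriors against brute-force Bayes.

Counting rules, per site with MRCA state $m$ and tip states $s_a, s_b$
(gaps, unknowns and sites below an optional posterior floor are skipped,
never imputed):

* convergent iff $s_a = s_b \neq m$;
* divergent iff $s_a \neq s_b$ and both differ from $m$ (default
  "both-changed" rule; a looser rule counting any $s_a \neq s_b$ is
  available via `divergent_rule = "any_different"` because the verbal
  definition admits both readings);
* single-lineage changes count as neither.

The default `posterior_floor = 0` applies no filter; it exists for
sensitivity analysis.  The pairwise response defaults to the genome-wide
total `C` (`response = "per_gene"` divides by the number of scored
genes); both conventions appear in practice and the choice does not
change the model structure.

## The pairwise convergence mixed model

For all $n(n-1)/2$ unordered pairs, the Gaussian model is

$$C_{ij} = \beta_0 + \beta_D D_{ij} + \beta_t t_{ij} + \beta_p
\mathrm{plunge}_{ij} + \beta_i \mathrm{island}_{ij} + \beta_{Dt} D_{ij}
t_{ij} + u_{a(ij)} + u_{b(ij)} + v_{m(ij)} + \varepsilon_{ij},$$

where $t$ is divergence time, the focal indicators are 1 only when both
tips carry the trait *and* the Fitch reconstruction puts their MRCA in
the ancestral (absent) state — i.e. independent origins — and the random
terms are: lineage in role a, lineage in role b (roles randomized by
`shuffle_pair_roles()` so each lineage appears evenly), and the pair's
MRCA node with covariance proportional to the phylogenetic covariance of
those internal nodes.  That node covariance is normalized to unit mean
diagonal so the variance component (and the phylogenetic signal ratio
$\sigma^2_{m} / (\sigma^2_m + \sigma^2_a + \sigma^2_b + \sigma^2_e)$) is
scale-free; a latent-scale variant adds $\pi^2/3$ to the denominator for
comparability with logit-scale formulations.

Default estimation is REML with the four variance components profiled
directly by Nelder-Mead on log variances — deterministic and testable.
A conjugate Gibbs sampler (`method = "mcmc"`, default $10^6$ iterations
with the first 25% discarded and thinning 10) mirrors the Bayesian
protocol with weakly-informative inverse-gamma priors
($a = b = 10^{-3}$); it reports posterior means, 95% credible intervals
and two-sided tail probabilities $2\min(P(\beta>0), P(\beta<0))$.  REML
p-values use t statistics on $n - p$ residual degrees of freedom (no
small-sample correction is applied, since none is canonical here).
The effect size $\eta^2$ for the focal term is computed from an ordinary
least-squares sequential ANOVA with the plunge term entered after `D`,
time and island, before the interaction.

Because counts are nonnegative, a `log1p` response transform is offered;
the default stays on the raw scale, matching the linear-model reading of
the analysis.  Calibration at the null ($\beta_p = 0$) and coverage of a
planted $\beta_p = 0.5$ are part of the acceptance tests.

## Demographic curve shapes

`parse_psmc_output()` rescales the final iteration block of a PSMC run:
$N_0 = \theta_0/(4\mu s)$ (bin size $s$ defaults to 100, the common
practice value; it is a parameter because the upstream binning is not
recoverable from the output), times $2 N_0 t_k g$ years with generation
time $g$, sizes $N_0\lambda_k$.  All trajectories live in years and
individuals; conversions happen only at parse time.

`common_grid()` evaluates every species' log-Ne as a right-continuous
step function on `n_points = 64` log-spaced times inside the common
support (log spacing because PSMC's resolution is logarithmic in time;
natural log for Ne).  `dpgls_rrpp()` then premultiplies the curve matrix
and the group design by $C^{-1/2}$ (symmetric inverse square root of the
tip covariance, eigenvalue floor $10^{-12}\max$), fits the multivariate
linear model, and assesses the group effect by residual randomization:
reduced-model (intercept-only) residual rows are permuted, and
$P_{rand} = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$.  With an
identity covariance this reduces exactly to a non-phylogenetic
permutation MANOVA, which the tests verify to $10^{-10}$.

## Selection gene sets, enrichment and PSG models

External codon-model and convergence tests enter as score tables; the
package's contribution is the combination logic.  The
adaptively-convergent set intersects three components: branch-site
foreground hits (BH FDR < 0.05) confirmed by the relaxed-selection test;
genes whose per-branch adaptive test is significant on at least two focal
lineages; and genes with residue-convergence posterior ≥ 0.8.  All
thresholds are arguments.  The confirmation percentage
($100\,|BS \cap RELAX| / |BS|$, one decimal) is reported alongside all
intersection counts.  Enrichment uses the exact hypergeometric upper tail
against a caller-supplied background with BH FDR over tested terms;
terms with zero overlap are not tested.

PSG counts per species are modelled by GLS with Pagel's $\lambda$
scaling the off-diagonal phylogenetic covariance, $\lambda$ profiled by
maximum likelihood on $[0,1]$ (golden-section via `optimize`, tolerance
$10^{-6}$, boundary candidates checked explicitly).  Note $\lambda$ is
unidentifiable on a star tree (off-diagonals vanish for every
$\lambda$); the meaningful "no signal" check is iid data fitted against
a structured tree, which drives $\hat\lambda$ to 0.  Bidirectional
AIC-based term selection (`stepwise_aic()`) respects marginality
(interactions only with their main effects) and is deterministic.
Pairwise PSG overlap between groups of species pairs reuses the pair
mixed-model machinery with group fixed effects; groups are summarized by
a compact letter display assigned greedily by descending mean — adequate
for the ≤ 6 groups this analysis meets; no letter-minimization is
attempted.  Group definitions are caller-supplied
(`default_pair_groups()` provides focal-plunge / focal-island /
background with plunge taking precedence) because the pooling convention
is a free choice.

## Relative-rate scan with permulations

`compute_rers()` regresses square-root gene branch lengths on
square-root master branch lengths per gene (branches matched by the tip
set they subtend; master branches below $10^{-6}$ excluded; genes with
fewer than 5 shared branches skipped) and takes centered residuals as
relative evolutionary rates.  This deliberately omits the weighted
heteroscedasticity correction of the full published method — the scan is
a simplified reimplementation.  The foreground statistic is a
tie-corrected Wilcoxon rank-sum z of foreground vs background RERs;
foreground branches are all branches on origin-to-tip paths including
each origin's stem branch, consistent with path-as-lineage semantics.
Permulation nulls re-draw the binary trait by simulating Brownian
histories and assigning the k top-ranked tips (optionally rejecting
draws until the origin count matches, capped at `max_tries`), then
recompute the statistic; empirical p-values use the $+1$-corrected
two-sided rule (one-sided options available) with BH q-values.  The
floor $1/(n_{perm}+1)$ is respected by construction; the default 500
permulations mirrors the analysis protocol.

## What the synthetic generators emulate — and what they do not

Every pipeline input can be generated with planted truth
(`simulate_tree_and_traits`, `simulate_alignment_with_convergence`,
`simulate_ne_trajectories`, `simulate_gene_tests_and_psgs`,
`simulate_gene_trees`, `simulate_pair_table`); all are pure functions of
their arguments and seed, and all emit the truth objects (site classes,
node states, planted gene sets, regime labels) needed for oracle tests.

* Trees are Yule (pure birth) rescaled to height 1 with exactly k trait
  origins on non-nested edges — by default 4 plunge and 5 island
  origins, the observed counts in the motivating system.
* Molecular convergence is injected by end-state attraction: on
  foreground branches, a convergent site's end state is replaced by a
  site-specific target amino acid with probability `attraction` (default
  0.5) for a `convergent_fraction` (default 0.05) of sites.  This is the
  minimal mechanism that produces excess `C` at matched `D` — precisely
  what the pair model measures — without selection-coefficient
  machinery.  Background sites follow the equal-rates model exactly
  (Gillespie simulation; at `attraction = 0` the convergent class is
  distributionally identical to background, which is tested).
* Ne trajectories are log-scale random walks on a 64-point log-time grid
  (1 kyr–10 Myr) anchored in the past, with total fluctuation SD 1.0
  (island) vs 0.4 (continental) and an island-only linear-in-log-time
  present-day decline of 0.9 (an order-of-magnitude crash over the most
  recent decade of the grid) — chosen to represent the drastic island
  declines these analyses target.  Walk increments are phylogenetically
  correlated across species (Brownian tip correlation): close relatives
  share demographic history, and this matches the covariance assumption
  of the downstream phylogenetic regression.  With independent species
  walks the dPGLS permutation test is anticonservative on structured
  trees; the correlated generator restores calibration
  (rejection ≈ α under the null), which the acceptance suite checks.
* Gene-test tables plant a known adaptively-convergent subset passing
  all four tests, null genes with uniform p-values and sub-threshold
  posteriors, PSG totals log-normal in plunge, mass, island and
  mass×island, and a term map whose first term covers exactly the
  planted subset.

What passing these tests does **not** show about real data: the
generators have no codon structure, indels, alignment error,
recombination, reference bias, or demographic-inference noise, and real
selection tests are correlated in ways the planted tables are not.  The
suite validates the *inference machinery* under the stated statistical
assumptions, not the upstream bioinformatics.

## Numerical choices and degenerate inputs

* Internal node ids are postorder indices of the ladderized tree, so the
  same Newick (up to rotation) always yields the same ids.
* Ultrametricity is enforced with a relative tolerance
  ($10^{-6}$ of tree height), since published timetrees carry rounding
  noise.
* Argmax ties in posteriors resolve alphabetically with a $10^{-9}$
  relative tolerance so exact symmetries are not broken by float
  round-off; Fitch ties resolve toward absence at the root and by
  parent-state inheritance elsewhere.
* The MRCA covariance in the mixed models gets a $10^{-8}$ ridge; an
  all-zero node covariance (every pair's MRCA at the root, e.g. star
  trees) falls back to the identity.
* Constant responses and 0/0 contrasts are handled explicitly (the REML
  objective returns a large finite penalty instead of NaN; undefined
  contrast p-values count as "no difference").
* All readers reject malformed input (ragged alignments, duplicated
  labels, non-binary traits, scores outside [0,1]) rather than coercing.

## Problem sizes used in validation

The shipped tests run the calibration studies at 15–16 tips (105–120
pairs) with 200 replicates, recovery studies at 100 replicates, the
oracle enumerations on 4–6-tip trees, and the acceptance script runs the
full chain once at 31 species with 25 genes × 150 sites, 999–500
permutations/permulations.  These sizes were chosen so the whole suite
completes in a few minutes while keeping every Monte-Carlo bound
well-powered; all of them are arguments, and nothing in the
implementation depends on them.

## Worked example

```{r example}
sim <- simulate_tree_and_traits(n_tips = 12, n_origins_plunge = 3,
                                n_origins_island = 3, seed = 7)
ga <- simulate_gene_alignments(sim$tree, sim$traits, n_genes = 5,
                               n_sites = 120, seed = 8,
                               reconstruction = "ml")
pt <- build_pair_table(sim$tree, ga$states, ga$alignments, sim$traits)
fit <- fit_pair_lmm(shuffle_pair_roles(pt, seed = 9), sim$tree)
fit
```

```{r example2}
traj <- simulate_ne_trajectories(sim$tree, sim$traits, seed = 10)
grp <- setNames(ifelse(sim$traits$island == 1, "island", "continent"),
                sim$traits$species)
dpgls_rrpp(common_grid(traj), grp, sim$tree, n_perm = 499, seed = 11)
```

## Known limitations

* The amino-acid model is exchangeable-equal-rates; no empirical matrix
  (WAG/LG) or rate heterogeneity across sites, and no codon models.
* The Gibbs sampler assumes conjugate Gaussian structure; no latent
  non-Gaussian responses (a Poisson/overdispersed likelihood is out of
  scope by design).
* The relative-rate scan omits the published method's variance
  weighting, so its statistics are comparable in rank but not in value.
* PGLS p-values use plain t distributions with $n - p$ degrees of
  freedom; no small-sample correction.
* The compact letter display is greedy, not minimal.
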