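Package: phyloconverge
Title: Genome-Wide Convergence, Demographic Curve Shape, and Selection
    Gene-Set Analysis on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying molecular convergence across a phylogeny:
    counting convergent and divergent amino-acid substitutions per lineage
    pair from reconstructed ancestral states (Felsenstein pruning under an
    equal-rates 20-state model, or Fitch parsimony), fitting phylogenetic
    linear mixed models of convergence counts with paired-lineage and MRCA
    random effects (REML or Gibbs sampling), comparing effective-population-
    size trajectory shapes between groups with a distance-based phylogenetic
    regression and residual-randomization permutation, intersecting
    positive-selection test outputs into adaptively-convergent gene sets
    with hypergeometric enrichment, Pagel's-lambda PGLS of positively
    selected gene counts with AIC-based stepwise model selection, and a
    relative-rate convergence scan with binary-trait permulation null
    distributions.  Includes parsers for PSMC output, Newick trees,
    amino-acid FASTA and tabular test results, and a synthetic-data
    generator reproducing the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    Biostrings,
    nlme,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
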