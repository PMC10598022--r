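# Readers and writers for the external representations the pipeline touches.
# One tabular dialect throughout: tab-delimited UTF-8 with a header row.

#' Registered gene-level test names
#'
#' The selection/convergence pipeline consumes externally computed test
#' results.  Six test kinds are registered: `"site"` (site-model test),
#' `"branch_site"` (branch-site foreground test), `"relax"`
#' (relaxed-selection confirmation), `"branch_adaptive"` (per-branch
#' adaptive test; the only per-branch test, so `branch_id` is required for
#' it and forbidden otherwise), `"residue_convergence"` (posterior
#' probability of convergent residues) and `"rate_convergence"` (relative
#' evolutionary rate test).
#'
#' @return Character vector of registered test names.
#' @export
registered_tests <- function() {
  c("site", "branch_site", "relax", "branch_adaptive",
    "residue_convergence", "rate_convergence")
}

per_branch_tests <- function() "branch_adaptive"

#' Read an amino-acid FASTA alignment
#'
#' Reads a FASTA file of aligned amino-acid sequences into a character
#' matrix (rows = sequences, columns = sites), upper-cased.  Gap (`-`) and
#' unknown (`X`) symbols are retained; an attribute `ambiguous` marks which
#' cells hold gap/unknown states.
#'
#' @param path Path to a FASTA file.
#' @return Character matrix with row names equal to sequence labels and an
#'   `ambiguous` logical matrix attribute.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- lapply(as.character(ape::read.FASTA(path, type = "AA")), toupper)
  labels <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(labels)) {
    stop("duplicate FASTA label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- labels[lens != stats::median(lens)]
    stop("ragged alignment; offending label(s): ", paste(bad, collapse = ", "))
  }
  aln <- do.call(rbind, seqs)
  rownames(aln) <- labels
  attr(aln, "ambiguous") <- matrix(!(aln %in% amino_acids()), nrow(aln),
                                   ncol(aln), dimnames = dimnames(aln))
  aln
}

#' Write an amino-acid alignment as FASTA
#'
#' @param aln Character matrix as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' The 20 standard amino acids, alphabetically
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Read a rooted Newick tree with canonical internal node ids
#'
#' Parses a Newick string via [ape::read.tree()], requires branch lengths
#' on every edge, ladderizes the tree and assigns internal node labels
#' `nd<k>` where `k` is the node's postorder index among internal nodes of
#' the ladderized tree, so identical Newick strings (up to rotation) always
#' yield identical ids.
#'
#' @param path Path to a Newick file (or a file containing one tree).
#' @return An object of class `phylo` with canonical `node.label`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unreadable Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("unreadable Newick file: ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  canonical_tree(tr)
}

#' Assign canonical internal node ids to a phylo object
#'
#' @param tr A `phylo` object with branch lengths on all edges.
#' @return The ladderized tree with `node.label` set to `nd<postorder index>`.
#' @export
canonical_tree <- function(tr) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      length(tr$edge.length) != nrow(tr$edge)) {
    stop("tree is missing branch lengths")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr <- ape::ladderize(tr, right = TRUE)
  n <- ape::Ntip(tr)
  po <- ape::reorder.phylo(tr, "postorder")
  # internal nodes in the order their outgoing edges are completed
  internal_order <- unique(po$edge[, 1L])
  rank <- integer(tr$Nnode)
  rank[internal_order - n] <- seq_along(internal_order)
  tr$node.label <- paste0("nd", rank)
  tr
}

#' Construct an effective-population-size trajectory
#'
#' A piecewise-constant Ne-vs-time function: `ne_values[k]` holds on
#' `[times[k], times[k+1])`, times in years before present, Ne in
#' individuals.
#'
#' @param species_label Species name.
#' @param times Strictly increasing numeric vector of time points (years).
#' @param ne_values Positive Ne values, same length as `times`.
#' @param mu Per-site per-year mutation rate used in scaling.
#' @param gen_time Generation time in years.
#' @return An object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(species_label, times, ne_values, mu = NA_real_,
                          gen_time = NA_real_) {
  times <- as.numeric(times)
  ne_values <- as.numeric(ne_values)
  if (length(times) != length(ne_values)) stop("times and ne_values differ in length")
  if (length(times) < 1L) stop("empty trajectory")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(ne_values)) || any(ne_values <= 0)) {
    stop("ne_values must be positive and finite")
  }
  structure(list(species_label = as.character(species_label), times = times,
                 ne_values = ne_values, mu = mu, gen_time = gen_time),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("Ne trajectory for %s: %d intervals, %.3g-%.3g years\n",
              x$species_label, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Right-continuous step-function convention: the value at `t` is the Ne of
#' the latest interval start not exceeding `t`.
#'
#' @param traj An [ne_trajectory()].
#' @param t Numeric vector of query times (years before present), each
#'   within the trajectory's support.
#' @return Numeric vector of Ne values.
#' @export
eval_trajectory <- function(traj, t) {
  if (any(t < traj$times[1L]) || any(t > max(traj$times))) {
    stop("query time outside trajectory support for ", traj$species_label)
  }
  traj$ne_values[findInterval(t, traj$times)]
}

#' Parse PSMC plain-text output into an Ne trajectory
#'
#' Uses the final iteration block of the standard PSMC text format.  With
#' \eqn{\theta_0} the block's estimate, bin size \eqn{s}, mutation rate
#' \eqn{\mu} and generation time \eqn{g}:
#' \deqn{N_0 = \theta_0 / (4 \mu s), \quad t_k^{years} = 2 N_0 t_k g,
#'       \quad Ne_k = N_0 \lambda_k .}
#'
#' @param path Path to a PSMC output file.
#' @param mu Per-site per-generation mutation rate.
#' @param gen_time Generation time in years (4.8 for kingfishers).
#' @param bin_size Consecutive-site bin size used when the PSMC input was
#'   built (default 100).
#' @param species_label Label for the trajectory; defaults to the file name
#'   without extension.
#' @return An [ne_trajectory()] in years and individuals.
#' @export
parse_psmc_output <- function(path, mu, gen_time, bin_size = 100,
                              species_label = NULL) {
  stopifnot(file.exists(path), mu > 0, gen_time > 0, bin_size > 0)
  if (is.null(species_label)) {
    species_label <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  rd <- grep("^RD\\b", lines)
  if (length(rd) == 0L) stop("no iteration block (RD lines) in ", path)
  block <- lines[rd[length(rd)]:length(lines)]
  end <- grep("^//", block)[1L]
  if (!is.na(end)) block <- block[seq_len(end - 1L)]
  tr_line <- grep("^TR\\b", block, value = TRUE)
  rs_lines <- grep("^RS\\b", block, value = TRUE)
  if (length(tr_line) == 0L || length(rs_lines) == 0L) {
    stop("incomplete iteration block in ", path)
  }
  theta0 <- as.numeric(strsplit(tr_line[1L], "\\s+")[[1L]][2L])
  if (!is.finite(theta0) || theta0 <= 0) stop("non-positive theta0 in ", path)
  rs <- do.call(rbind, lapply(strsplit(rs_lines, "\\s+"), function(f) {
    as.numeric(f[3:4])  # t_k, lambda_k
  }))
  n0 <- theta0 / (4 * mu * bin_size)
  ne_trajectory(species_label,
                times = 2 * n0 * rs[, 1L] * gen_time,
                ne_values = n0 * rs[, 2L],
                mu = mu, gen_time = gen_time)
}

#' Read a two-column time/Ne table as a trajectory
#'
#' @param path TSV with header columns `time` (years) and `ne`.
#' @param species_label Label; defaults to file name without extension.
#' @return An [ne_trajectory()].
#' @export
read_ne_table <- function(path, species_label = NULL) {
  if (is.null(species_label)) species_label <- sub("\\.[^.]*$", "", basename(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "ne") %in% names(d))) stop("expected columns time, ne")
  ne_trajectory(species_label, d$time, d$ne)
}

#' Read a species trait table
#'
#' @param path TSV with header columns `species`, `plunge` (0/1), `island`
#'   (0/1) and optionally `mass` (ln grams; `NA` allowed).
#' @param tree Optional `phylo`; if supplied, species must match tree tips
#'   exactly.
#' @return A `data.frame` with one row per species (class `trait_map`).
#' @export
read_trait_table <- function(path, tree = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trait_map(d, tree)
}

#' Validate a trait table against its contract (and optionally a tree)
#'
#' @param d Data frame with columns `species`, `plunge`, `island`, and
#'   optionally `mass`.
#' @param tree Optional `phylo` whose tip labels must match `d$species`.
#' @return `d`, with class `trait_map` prepended.
#' @export
validate_trait_map <- function(d, tree = NULL) {
  need <- c("species", "plunge", "island")
  if (!all(need %in% names(d))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$species)) {
    stop("duplicated species row(s): ",
         paste(unique(d$species[duplicated(d$species)]), collapse = ", "))
  }
  for (col in c("plunge", "island")) {
    if (!all(d[[col]] %in% c(0, 1))) {
      stop("non-binary value in column '", col, "'")
    }
  }
  if (!is.null(tree)) {
    missing_tree <- setdiff(d$species, tree$tip.label)
    missing_tab <- setdiff(tree$tip.label, d$species)
    if (length(missing_tree) || length(missing_tab)) {
      stop("species/tree mismatch; absent from tree: [",
           paste(missing_tree, collapse = ", "), "]; absent from table: [",
           paste(missing_tab, collapse = ", "), "]")
    }
  }
  if (!"mass" %in% names(d)) d$mass <- NA_real_
  class(d) <- c("trait_map", class(d))
  d
}

#' Read a gene-test result table
#'
#' @param path TSV with header columns `gene_id`, `test_name`, optional
#'   `branch_id`, `score`, optional `qvalue`.
#' @return Data frame of validated records.
#' @export
read_gene_test_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(gene_id = "character"))
  validate_gene_tests(d)
}

validate_gene_tests <- function(d) {
  need <- c("gene_id", "test_name", "score")
  if (!all(need %in% names(d))) {
    stop("gene-test table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(d$test_name), registered_tests())
  if (length(bad)) stop("unknown test_name(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(d$score)) || any(d$score < 0 | d$score > 1)) {
    stop("score outside [0, 1]")
  }
  if (!"branch_id" %in% names(d)) d$branch_id <- NA_character_
  pb <- d$test_name %in% per_branch_tests()
  if (any(pb & (is.na(d$branch_id) | !nzchar(d$branch_id)))) {
    stop("per-branch test rows must carry branch_id")
  }
  if (any(!pb & !is.na(d$branch_id))) {
    stop("branch_id given for a test that is not per-branch")
  }
  if ("qvalue" %in% names(d)) {
    ok <- is.na(d$qvalue) | (d$qvalue >= 0 & d$qvalue <= 1)
    if (!all(ok)) stop("qvalue outside [0, 1]")
  } else {
    d$qvalue <- NA_real_
  }
  d[c("gene_id", "test_name", "branch_id", "score", "qvalue")]
}

#' Write gene-test records (round-trip stable with [read_gene_test_table()])
#'
#' @param records Data frame of gene-test records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- validate_gene_tests(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a generic data frame as the package's TSV dialect
#' @param d Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
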