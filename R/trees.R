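#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise distances d = -3/4 ln(1 - 4/3 p) with p the mismatch fraction
#' over shared ungapped sites. Saturated pairs (p >= 0.75) are reported at
#' `cap` with a warning, keeping the matrix finite.
#'
#' @param aln nucleotide or codon alignment (named character vector).
#' @param cap distance assigned to saturated pairs.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(aln, cap = 5.0) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    ns <- sum(ok)
    p <- if (ns == 0) NA_real_ else sum(m[i, ok] != m[j, ok]) / ns
    d <- if (is.na(p) || p >= 0.75) {
      saturated <- TRUE
      cap
    } else {
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  if (saturated)
    warning("saturated pair(s) (p >= 0.75) set to cap = ", cap)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; on additive matrices the
#' generating topology is recovered exactly.
#'
#' @param dist_matrix symmetric distance matrix (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(dist_matrix) {
  if (!isSymmetric(unname(as.matrix(dist_matrix)), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (nrow(dist_matrix) < 3) stop("need at least 3 taxa")
  ape::nj(stats::as.dist(dist_matrix))
}

#' Root a tree on a designated outgroup tip
#' @param tree `phylo`.
#' @param outgroup tip label.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not among tips")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# default tree builder used by bootstrap and pipeline stages
build_nj <- function(aln, cap = 5.0) {
  nj_tree(suppressWarnings(jc_distance_matrix(aln, cap = cap)))
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the tree for
#' each replicate with `tree_fun`, and annotates each internal edge of
#' the original tree with the percentage of replicates containing the
#' same bipartition.
#'
#' @param aln alignment (named character vector).
#' @param n_replicates bootstrap replicates; 0 returns the plain tree.
#' @param seed integer seed for the resampling.
#' @param tree_fun function(alignment) -> `phylo`; defaults to
#'   neighbor-joining on Jukes-Cantor distances.
#' @param codon resample whole codons rather than single columns.
#' @return `phylo` with `node.label` supports in \[0, 100\] (internal
#'   nodes; root label empty).
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              tree_fun = build_nj, codon = FALSE) {
  tree <- tree_fun(aln)
  if (n_replicates == 0L) return(tree)
  m <- aln_matrix(aln)
  unit <- if (codon) 3L else 1L
  ncolu <- ncol(m) %/% unit
  if (ncolu < 1) stop("alignment has no columns to resample")
  reps <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    pick <- sample.int(ncolu, ncolu, replace = TRUE)
    cols <- as.vector(outer(seq_len(unit), (pick - 1L) * unit, "+"))
    sub <- m[, cols, drop = FALSE]
    rows <- apply(sub, 1L, paste, collapse = "")
    tree_fun(stats::setNames(rows, names(aln)))
  }))
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / n_replicates, 1)
  tree
}

# quartet state of every 4-subset of taxa in a tree: 1 = (1,2)|(3,4),
# 2 = (1,3)|(2,4), 3 = (1,4)|(2,3), 0 = unresolved; subsets are columns
# of combn(taxa, 4) in taxon order.
quartet_states <- function(tree, taxa) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- stats::cophenetic(t2)[taxa, taxa]
  qs <- utils::combn(length(taxa), 4L)
  apply(qs, 2L, function(q) {
    s <- c(D[q[1], q[2]] + D[q[3], q[4]],
           D[q[1], q[3]] + D[q[2], q[4]],
           D[q[1], q[4]] + D[q[2], q[3]])
    mn <- min(s)
    if (sum(s == mn) > 1) 0L else which.min(s)
  })
}

#' Quartet-score species tree by exhaustive search
#'
#' Returns the unrooted topology over `taxa` that maximizes the number of
#' induced quartets shared with the input gene trees, by scoring every
#' unrooted binary topology (feasible for n <= 8). This is a small-n
#' summary-coalescent estimate in the spirit of quartet-based species
#' tree methods.
#'
#' @param gene_trees list of `phylo` gene trees whose tip labels cover
#'   `taxa` (extra tips are ignored; trees missing a taxon contribute only
#'   their resolved quartets).
#' @param taxa taxon labels (3 < n <= 8).
#' @return `phylo`, with attributes `score` (quartets shared) and
#'   `max_score` (n_trees x choose(n, 4)).
#' @export
quartet_species_tree <- function(gene_trees, taxa) {
  n <- length(taxa)
  if (n > 8) stop("exhaustive quartet search limited to 8 taxa; subsample")
  if (n < 4) stop("need at least 4 taxa")
  gene_states <- vapply(gene_trees, function(tr) {
    if (!all(taxa %in% tr$tip.label))
      stop("gene tree missing taxa: ",
           paste(setdiff(taxa, tr$tip.label), collapse = ","))
    quartet_states(tr, taxa)
  }, integer(choose(n, 4L)))
  if (is.null(dim(gene_states)))
    gene_states <- matrix(gene_states, nrow = 1L)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  scores <- vapply(cands, function(tr) {
    st <- quartet_states(tr, taxa)
    sum(gene_states == st & gene_states != 0L)
  }, numeric(1))
  best <- which.max(scores)
  out <- cands[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "max_score") <- length(gene_trees) * choose(n, 4L)
  out
}
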