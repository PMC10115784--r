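#' Build orthogroups from protein similarity
#'
#' All-vs-all protein comparison restricted to candidate pairs that share
#' enough exact CDS k-mers, scored by local alignment (BLOSUM62, affine
#' gaps). Pairs passing the identity and coverage thresholds in both
#' directions (the scoring is symmetric) become edges; orthogroups are
#' the connected components of that reciprocal-hit graph, so unmatched
#' genes form singleton groups.
#'
#' @param genes data.frame with columns `gene`, `genome`, `cds`.
#' @param min_identity minimum fraction of identical aligned residues.
#' @param min_coverage minimum fraction of the shorter protein covered by
#'   the local alignment.
#' @param kmer_k,min_shared_kmers CDS k-mer prefilter: only pairs sharing
#'   at least `min_shared_kmers` distinct `kmer_k`-mers are aligned.
#' @return list with `groups` (list of gene-id vectors, largest first)
#'   and `membership` (named vector gene -> group index).
#' @export
build_orthogroups <- function(genes, min_identity = 0.4, min_coverage = 0.5,
                              kmer_k = 10L, min_shared_kmers = 30L) {
  if (nrow(genes) == 0)
    return(list(groups = list(), membership = integer(0)))
  ok <- nchar(genes$cds) %% 3L == 0L & nchar(genes$cds) >= 3L
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) with untranslatable CDS skipped: ",
            paste(utils::head(genes$gene[!ok], 5), collapse = ","))
    genes <- genes[ok, , drop = FALSE]
  }
  n <- nrow(genes)
  prot <- translate_cds(stats::setNames(genes$cds, genes$gene))

  # candidate pairs by shared exact CDS k-mers
  km <- lapply(genes$cds, function(s) {
    unique(substring(s, seq_len(nchar(s) - kmer_k + 1L),
                     seq_len(nchar(s) - kmer_k + 1L) + kmer_k - 1L))
  })
  DT <- data.table::data.table(
    kmer = unlist(km),
    gi = rep.int(seq_len(n), lengths(km)))
  data.table::setkey(DT, kmer)
  J <- DT[DT, on = "kmer", allow.cartesian = TRUE]
  J <- J[J$gi < J$i.gi, ]
  shared <- J[, list(nsh = .N), by = c("gi", "i.gi")]
  shared <- shared[shared$nsh >= min_shared_kmers, ]

  edges <- matrix(integer(0), ncol = 2)
  if (nrow(shared)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    mat <- get("BLOSUM62", envir = environment())
    keep <- logical(nrow(shared))
    aa <- Biostrings::AAStringSet(prot)
    for (i in seq_len(nrow(shared))) {
      p <- aa[[shared$gi[i]]]
      s <- aa[[shared$i.gi[i]]]
      al <- Biostrings::pairwiseAlignment(
        p, s, type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 0.5)
      w <- Biostrings::nchar(al)
      ident <- Biostrings::nmatch(al) / w
      cov <- w / min(length(p), length(s))
      keep[i] <- ident >= min_identity && cov >= min_coverage
    }
    edges <- cbind(shared$gi[keep], shared$i.gi[keep])
  }
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) gr <- igraph::add_edges(gr, t(edges))
  comp <- igraph::components(gr)$membership
  groups <- split(genes$gene, comp)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  names(groups) <- paste0("OG", seq_along(groups))
  membership <- stats::setNames(
    rep(seq_along(groups), vapply(groups, length, integer(1))),
    unlist(groups, use.names = FALSE))
  list(groups = groups, membership = membership)
}

#' Extract strictly single-copy orthogroups
#'
#' Returns the orthogroups with exactly one member in every genome of
#' `genome_set`; groups with a missing genome or any duplicated copy are
#' excluded.
#'
#' @param orthogroups result of [build_orthogroups()].
#' @param genes the gene table used to build the orthogroups.
#' @param genome_set genome labels that must each contribute one copy.
#' @return list of gene-id vectors (one per retained group).
#' @export
find_single_copy_genes <- function(orthogroups, genes, genome_set) {
  genome_of <- stats::setNames(genes$genome, genes$gene)
  Filter(function(g) {
    tab <- table(factor(genome_of[g], levels = genome_set))
    all(tab == 1L) && length(g) == length(genome_set)
  }, orthogroups$groups)
}

#' Cross-genome homolog pairs from orthogroups
#'
#' Builds the gene-pair input for collinear chaining: all between-genome
#' pairs of genes sharing an orthogroup, after collapsing tandem arrays
#' (same-orthogroup neighbors within `tandem_rank` gene ranks on one
#' chromosome) to their lowest-rank representative.
#'
#' @param genes gene table (columns `gene`, `genome`, `chrom`, `rank`).
#' @param orthogroups result of [build_orthogroups()].
#' @param genome1,genome2 the two genomes to pair.
#' @param tandem_rank maximum rank distance defining a tandem array.
#' @return data.frame with columns `gene1`, `gene2`, `chrom1`, `chrom2`,
#'   `rank1`, `rank2`.
#' @export
homolog_pairs <- function(genes, orthogroups, genome1, genome2,
                          tandem_rank = 2L) {
  g <- genes[genes$genome %in% c(genome1, genome2), ]
  g$og <- orthogroups$membership[g$gene]
  g <- g[!is.na(g$og), ]
  # collapse tandem duplicates per genome (keep lowest-rank representative)
  g <- g[order(g$genome, g$chrom, g$rank), ]
  n <- nrow(g)
  if (n > 1) {
    i <- 2:n
    j <- i - 1L
    tandem <- g$genome[i] == g$genome[j] & g$chrom[i] == g$chrom[j] &
      g$og[i] == g$og[j] & (g$rank[i] - g$rank[j]) <= tandem_rank
    g <- g[c(TRUE, !tandem), ]
  }
  a <- g[g$genome == genome1, ]
  b <- g[g$genome == genome2, ]
  sp <- split(seq_len(nrow(b)), b$og)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    j <- sp[[as.character(a$og[i])]]
    if (is.null(j)) return(NULL)
    data.frame(gene1 = a$gene[i], gene2 = b$gene[j],
               chrom1 = a$chrom[i], chrom2 = b$chrom[j],
               rank1 = a$rank[i], rank2 = b$rank[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene1 = character(0), gene2 = character(0),
                      chrom1 = character(0), chrom2 = character(0),
                      rank1 = integer(0), rank2 = integer(0))
  out
}
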