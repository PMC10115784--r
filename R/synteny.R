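#' Chain collinear gene pairs into syntenic blocks
#'
#' Dynamic-programming chaining of homolog gene pairs in rank space, in
#' the style of collinearity callers such as MCScanX. Within every
#' chromosome pair and for both orientations, the score of a chain
#' ending at pair i is `score(i) = match_score + max(0, max_j score(j) -
#' gap_penalty * ((rank1_i - rank1_j - 1) + (rank2_i - rank2_j - 1)))`
#' over predecessors j with strictly increasing ranks on both sides and
#' rank gaps of at most `max_gap_genes`. Chains are extracted highest
#' score first, each pair belonging to at most one block (ties broken by
#' lexicographic order of the block's first gene for determinism), and
#' blocks shorter than `min_block_genes` pairs are discarded.
#'
#' @param pairs data.frame from [homolog_pairs()] (columns `gene1`,
#'   `gene2`, `chrom1`, `chrom2`, `rank1`, `rank2`).
#' @param match_score score per chained pair.
#' @param gap_penalty penalty per skipped gene rank on either side.
#' @param max_gap_genes maximum rank gap between consecutive chain pairs.
#' @param min_block_genes minimum pairs per reported block.
#' @return list with `blocks` (data.frame block_id, chrom1, chrom2,
#'   orientation, score, n_genes) and `members` (data.frame block_id,
#'   gene1, gene2, rank1, rank2).
#' @export
chain_collinear_blocks <- function(pairs, match_score = 50, gap_penalty = 1,
                                   max_gap_genes = 25L, min_block_genes = 5L) {
  empty <- list(
    blocks = data.frame(block_id = character(0), chrom1 = character(0),
                        chrom2 = character(0), orientation = character(0),
                        score = numeric(0), n_genes = integer(0)),
    members = data.frame(block_id = character(0), gene1 = character(0),
                         gene2 = character(0), rank1 = integer(0),
                         rank2 = integer(0)))
  if (nrow(pairs) == 0) return(empty)
  blocks <- list()
  members <- list()
  bid <- 0L
  for (key in sort(unique(paste(pairs$chrom1, pairs$chrom2, sep = "\r")))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    pp <- pairs[pairs$chrom1 == parts[1] & pairs$chrom2 == parts[2], ]
    cand <- list()
    for (orient in c("same", "inverted")) {
      q <- pp
      q$r2 <- if (orient == "same") q$rank2 else -q$rank2
      q <- q[order(q$rank1, q$r2, q$gene1, q$gene2), ]
      np <- nrow(q)
      sc <- rep(match_score, np)
      prev <- rep(NA_integer_, np)
      for (i in seq_len(np)) {
        for (j in seq_len(i - 1L)) {
          g1 <- q$rank1[i] - q$rank1[j] - 1L
          g2 <- abs(q$r2[i] - q$r2[j]) - 1L
          if (q$rank1[j] >= q$rank1[i] || q$r2[j] >= q$r2[i]) next
          if (g1 > max_gap_genes || g2 > max_gap_genes) next
          s <- sc[j] - gap_penalty * (g1 + g2) + match_score
          if (s > sc[i]) {
            sc[i] <- s
            prev[i] <- j
          }
        }
      }
      cand[[orient]] <- list(q = q, sc = sc, prev = prev, orient = orient)
    }
    # extract non-overlapping chains, best score first
    ends <- do.call(rbind, lapply(cand, function(cc) {
      data.frame(orient = cc$orient, i = seq_along(cc$sc), sc = cc$sc,
                 g1 = cc$q$gene1, stringsAsFactors = FALSE)
    }))
    ends <- ends[order(-ends$sc, ends$g1, ends$orient), ]
    used <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(ends))) {
      cc <- cand[[ends$orient[r]]]
      chain <- integer(0)
      i <- ends$i[r]
      while (!is.na(i)) {
        chain <- c(i, chain)
        i <- cc$prev[i]
      }
      keys <- paste0(cc$q$gene1[chain], "\r", cc$q$gene2[chain])
      if (any(vapply(keys, exists, logical(1), envir = used)) ||
          length(chain) < min_block_genes)
        next
      for (k in keys) assign(k, TRUE, envir = used)
      bid <- bid + 1L
      id <- sprintf("block%04d", bid)
      blocks[[id]] <- data.frame(
        block_id = id, chrom1 = parts[1], chrom2 = parts[2],
        orientation = ends$orient[r],
        score = cc$sc[ends$i[r]], n_genes = length(chain),
        stringsAsFactors = FALSE)
      members[[id]] <- data.frame(
        block_id = id, gene1 = cc$q$gene1[chain], gene2 = cc$q$gene2[chain],
        rank1 = cc$q$rank1[chain], rank2 = cc$q$rank2[chain],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks)) return(empty)
  list(blocks = do.call(rbind, unname(blocks)),
       members = do.call(rbind, unname(members)))
}

#' Extract anchor groups at an exact copy ratio
#'
#' Connects genes through syntenic block membership (all genome pairs)
#' and keeps the connected components whose per-genome copy counts match
#' `ratio` exactly -- e.g. `c(out = 1, tet = 2, oct = 4)` for the
#' diploid:tetraploid:octoploid anchor unit. Genes in regions with
#' missing or surplus copies are thereby excluded, and no gene occurs in
#' two groups.
#'
#' @param block_members data.frame(s) of block member pairs (the
#'   `members` element of [chain_collinear_blocks()]), rbind-ed over all
#'   genome pairs.
#' @param genes gene table (columns `gene`, `genome`, `chrom`).
#' @param ratio named integer vector of required copies per genome.
#' @return list with `groups` (data.frame anchor_id, n_genes) and
#'   `members` (data.frame anchor_id, gene, genome, chrom).
#' @export
extract_anchor_groups <- function(block_members, genes,
                                  ratio = c(out = 1, tet = 2, oct = 4)) {
  if (!all(names(ratio) %in% unique(genes$genome)))
    stop("ratio names (", paste(names(ratio), collapse = ","),
         ") do not match genome labels")
  empty <- list(groups = data.frame(anchor_id = character(0),
                                    n_genes = integer(0)),
                members = data.frame(anchor_id = character(0),
                                     gene = character(0),
                                     genome = character(0),
                                     chrom = character(0)))
  if (is.null(block_members) || nrow(block_members) == 0) return(empty)
  ids <- unique(c(block_members$gene1, block_members$gene2))
  idx <- stats::setNames(seq_along(ids), ids)
  gr <- igraph::make_empty_graph(length(ids), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(idx[block_members$gene1],
                                    idx[block_members$gene2]))
  comp <- igraph::components(gr)$membership
  genome_of <- stats::setNames(genes$genome, genes$gene)
  chrom_of <- stats::setNames(genes$chrom, genes$gene)
  groups <- split(ids, comp)
  keep <- vapply(groups, function(g) {
    tab <- table(factor(genome_of[g], levels = names(ratio)))
    !anyNA(genome_of[g]) && all(tab == ratio)
  }, logical(1))
  groups <- groups[keep]
  if (!length(groups)) return(empty)
  names(groups) <- sprintf("anchor%05d", seq_along(groups))
  members <- data.frame(
    anchor_id = rep(names(groups), vapply(groups, length, integer(1))),
    gene = unlist(groups, use.names = FALSE), stringsAsFactors = FALSE)
  members$genome <- unname(genome_of[members$gene])
  members$chrom <- unname(chrom_of[members$gene])
  list(groups = data.frame(anchor_id = names(groups),
                           n_genes = vapply(groups, length, integer(1)),
                           row.names = NULL),
       members = members)
}

#' Full synteny stage: orthogroups, blocks and anchor groups
#'
#' Convenience wrapper running [build_orthogroups()], [homolog_pairs()]
#' and [chain_collinear_blocks()] for every genome pair, then
#' [extract_anchor_groups()].
#'
#' @param genes gene table (columns `gene`, `genome`, `chrom`, `rank`,
#'   `cds`).
#' @param ratio required per-genome copy counts.
#' @param ... passed to [chain_collinear_blocks()].
#' @return list with `orthogroups`, `blocks`, `anchors`.
#' @export
synteny_anchor_groups <- function(genes, ratio = c(out = 1, tet = 2, oct = 4),
                                  ...) {
  og <- build_orthogroups(genes)
  genomes <- names(ratio)
  combos <- utils::combn(genomes, 2)
  blocks <- list()
  members <- list()
  for (i in seq_len(ncol(combos))) {
    pr <- homolog_pairs(genes, og, combos[1, i], combos[2, i])
    bl <- chain_collinear_blocks(pr, ...)
    if (nrow(bl$blocks)) {
      bl$blocks$genome1 <- combos[1, i]
      bl$blocks$genome2 <- combos[2, i]
      pfx <- paste0(combos[1, i], "_", combos[2, i], "_")
      bl$blocks$block_id <- paste0(pfx, bl$blocks$block_id)
      bl$members$block_id <- paste0(pfx, bl$members$block_id)
      blocks[[i]] <- bl$blocks
      members[[i]] <- bl$members
    }
  }
  blocks <- do.call(rbind, blocks)
  members <- do.call(rbind, members)
  anchors <- extract_anchor_groups(members, genes, ratio)
  list(orthogroups = og, blocks = blocks, block_members = members,
       anchors = anchors)
}
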