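as_seq_vector <- function(genome) {
  if (inherits(genome, "polyploid_sim"))
    stop("pass a specific genome, e.g. sim$genomes$oct")
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    genome
  } else stop("genome must be a DNAStringSet or named character vector")
}

#' Count canonical k-mers per chromosome
#'
#' Strand-canonical (lexicographically smaller of k-mer and reverse
#' complement) counting; windows containing ambiguous bases are skipped.
#' Only k-mers whose genome-wide total reaches `min_total` are kept as
#' columns, which at repetitive-k-mer thresholds keeps the matrix small.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector of
#'   chromosome sequences.
#' @param k odd k-mer size, 11 <= k <= 31 (odd so that no k-mer is its
#'   own reverse complement).
#' @param min_total minimum genome-wide count for a k-mer column.
#' @return object of class `kmer_matrix`: list with `kmers`, `counts`
#'   (chromosomes x k-mers), `lengths`, `valid` (counted windows per
#'   chromosome), `k`.
#' @export
count_kmers <- function(genome, k = 15L, min_total = 1L) {
  seqs <- as_seq_vector(genome)
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (even k makes canonicalization ambiguous)")
  if (k < 11L || k > 31L) stop("k must be between 11 and 31")
  res <- cpp_kmer_matrix(unname(seqs), k, as.integer(min_total))
  counts <- res$counts
  dimnames(counts) <- list(names(seqs), res$kmers)
  structure(list(kmers = res$kmers, counts = counts,
                 lengths = nchar(seqs),
                 valid = stats::setNames(res$valid, names(seqs)), k = k),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("kmer_matrix: ", nrow(x$counts), " sequence(s) x ", ncol(x$counts),
      " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}

# per-bp normalized count matrix
normalize_kmer_counts <- function(km) {
  sweep(km$counts, 1L, pmax(km$valid, 1), "/")
}

#' Select differential (subgenome-specific) k-mers
#'
#' A k-mer is assigned to the chromosome group with the highest per-bp
#' normalized mean count and retained if that mean exceeds `min_fold`
#' times the second-highest group's mean and the genome-wide raw count is
#' at least `min_count`. These differential repetitive k-mers are assumed
#' to have expanded during a subgenome's independent
#' divergence-to-hybridization period.
#'
#' @param km a [count_kmers()] matrix.
#' @param groups named vector mapping chromosomes to tentative groups
#'   (e.g. the output of [cluster_chromosomes()]); defaults to one group
#'   per chromosome.
#' @param min_fold minimum fold difference between top and runner-up
#'   group means.
#' @param min_count minimum genome-wide raw count.
#' @return named list (one element per group) of k-mer character vectors.
#' @export
select_differential_kmers <- function(km, groups = NULL, min_fold = 2,
                                      min_count = 10L) {
  if (ncol(km$counts) == 0) return(list())
  if (is.null(groups))
    groups <- stats::setNames(rownames(km$counts), rownames(km$counts))
  norm <- normalize_kmer_counts(km)
  glab <- groups[rownames(norm)]
  gm <- rowsum(norm, glab) / as.vector(table(glab)[sort(unique(glab))])
  top <- apply(gm, 2L, which.max)
  top_val <- gm[cbind(top, seq_len(ncol(gm)))]
  second <- apply(gm, 2L, function(v) max(v[-which.max(v)], 0))
  total <- colSums(km$counts)
  keep <- top_val > min_fold * second & total >= min_count & top_val > 0
  sp <- split(colnames(gm)[keep], rownames(gm)[top[keep]])
  out <- stats::setNames(vector("list", nrow(gm)), rownames(gm))
  for (g in names(sp)) out[[g]] <- sp[[g]]
  lapply(out, function(x) x %||% character(0))
}

#' Assign chromosomes to subgenomes by k-means
#'
#' k-means on per-bp normalized, per-k-mer standardized count vectors,
#' taking the best of `n_restarts` random starts by within-cluster sum of
#' squares. Cluster labels are renamed canonically (`S1` = largest
#' cluster, ties broken by the alphabetically first member chromosome)
#' so that the assignment is deterministic under the seed.
#'
#' @param km a [count_kmers()] matrix, ideally restricted to differential
#'   k-mers (`kmers` argument).
#' @param n_subgenomes number of clusters (<= number of chromosomes).
#' @param kmers optional character vector restricting the columns used.
#' @param n_restarts k-means restarts.
#' @param seed integer seed.
#' @return named character vector chromosome -> subgenome label.
#' @export
cluster_chromosomes <- function(km, n_subgenomes = 4L, kmers = NULL,
                                n_restarts = 10L, seed = 1L) {
  x <- normalize_kmer_counts(km)
  if (!is.null(kmers)) x <- x[, colnames(x) %in% kmers, drop = FALSE]
  if (ncol(x) == 0) stop("no k-mer columns to cluster on")
  if (n_subgenomes > nrow(x))
    stop("more subgenomes than chromosomes")
  if (any(rowSums(x) == 0))
    stop("chromosome(s) with no counted k-mers: ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ","),
         "; adjust k or count thresholds")
  sdv <- apply(x, 2L, stats::sd)
  x <- sweep(sweep(x, 2L, colMeans(x)), 2L, pmax(sdv, 1e-12), "/")
  fit <- with_seed(seed,
                   stats::kmeans(x, centers = n_subgenomes,
                                 nstart = n_restarts, iter.max = 100L))
  cl <- fit$cluster
  size <- table(cl)
  firsts <- vapply(split(names(cl), cl), function(ch) sort(ch)[1],
                   character(1))
  ord <- order(-as.integer(size), firsts)
  relabel <- stats::setNames(paste0("S", seq_along(ord)),
                             names(size)[ord])
  stats::setNames(unname(relabel[as.character(cl)]), names(cl))
}

#' Window-level enrichment of subgenome-specific k-mers
#'
#' Tiles each chromosome into `window_size` windows and tests every
#' window x subgenome combination for enrichment of that subgenome's
#' specific k-mers with an exact hypergeometric upper tail (drawing the
#' window's specific-k-mer occurrences from the genome-wide pool),
#' followed by Benjamini-Hochberg FDR across all tests. A window's
#' enrichment label is the subgenome with the smallest q-value below
#' `alpha`, or none.
#'
#' @param genome chromosome sequences.
#' @param sets named list of specific k-mer sets per subgenome.
#' @param window_size window size in bp (>= k).
#' @param k k-mer size used to build `sets`.
#' @param alpha FDR threshold.
#' @return data.frame with one row per window: `chrom`, `window`
#'   (0-based), `start`, `end`, one hit-count column per subgenome,
#'   `total`, `label`, `p`, `q` (of the labeled set, NA if none).
#' @export
window_enrichment <- function(genome, sets, window_size = 12500L, k = 15L,
                              alpha = 0.05) {
  seqs <- as_seq_vector(genome)
  if (window_size < k) stop("window_size must be at least k")
  labs <- names(sets)
  rows <- lapply(names(seqs), function(cn) {
    wh <- cpp_window_set_hits(seqs[[cn]], as.integer(k), unname(sets),
                              window_size)
    nw <- nrow(wh$hits)
    df <- data.frame(chrom = cn, window = seq_len(nw) - 1L,
                     start = (seq_len(nw) - 1L) * window_size,
                     end = pmin(seq_len(nw) * window_size, nchar(seqs[[cn]])),
                     stringsAsFactors = FALSE)
    colnames(wh$hits) <- labs
    cbind(df, wh$hits)
  })
  win <- do.call(rbind, rows)
  hitmat <- as.matrix(win[, labs, drop = FALSE])
  win$total <- rowSums(hitmat)
  M <- colSums(hitmat)          # genome-wide occurrences per set
  N <- sum(M)                   # all specific-k-mer occurrences
  pmat <- matrix(1, nrow(win), length(labs), dimnames = list(NULL, labs))
  for (s in seq_along(labs)) {
    pmat[, s] <- stats::phyper(hitmat[, s] - 1L, M[s], N - M[s],
                               win$total, lower.tail = FALSE)
  }
  qmat <- matrix(stats::p.adjust(pmat, method = "BH"), nrow(win),
                 dimnames = dimnames(pmat))
  pick <- apply(qmat, 1L, which.min)
  qbest <- qmat[cbind(seq_len(nrow(win)), pick)]
  win$label <- ifelse(qbest < alpha & win$total > 0, labs[pick],
                      NA_character_)
  win$p <- pmat[cbind(seq_len(nrow(win)), pick)]
  win$q <- qbest
  win$p[is.na(win$label)] <- NA_real_
  win$q[is.na(win$label)] <- NA_real_
  win
}

#' Call homoeologous exchange segments from window enrichment
#'
#' Flags maximal runs of consecutive windows whose enrichment label
#' differs from the host chromosome's subgenome, bridging at most
#' `max_bridge_windows` interior unlabeled windows; runs shorter than
#' `min_exchange_windows` are discarded (the analogue, at analysis
#' scale, of excluding short exchanges). The donor is the run's modal
#' enrichment label.
#'
#' @param enrichment output of [window_enrichment()].
#' @param assignment named vector chromosome -> host subgenome label.
#' @param min_exchange_windows minimum run length in windows.
#' @param max_bridge_windows unlabeled windows tolerated inside a run.
#' @return data.frame with columns `chrom`, `start`, `end`, `host`,
#'   `donor`, `n_windows`, `length`.
#' @export
call_exchanges <- function(enrichment, assignment, min_exchange_windows = 5L,
                           max_bridge_windows = 1L) {
  out <- list()
  for (cn in unique(enrichment$chrom)) {
    e <- enrichment[enrichment$chrom == cn, ]
    e <- e[order(e$window), ]
    host <- assignment[[cn]]
    discord <- !is.na(e$label) & e$label != host
    idx <- which(discord)
    if (!length(idx)) next
    # group discordant windows, bridging short gaps of unlabeled windows
    # only (a host-labeled or other-labeled interior window breaks a run)
    brk <- vapply(seq_len(length(idx) - 1L), function(i) {
      if (idx[i + 1L] - idx[i] <= 1L) return(FALSE)
      gap <- (idx[i] + 1L):(idx[i + 1L] - 1L)
      length(gap) > max_bridge_windows || any(!is.na(e$label[gap]))
    }, logical(1))
    grp <- cumsum(c(1L, brk))
    for (g in unique(grp)) {
      w <- idx[grp == g]
      if (length(w) < min_exchange_windows) next
      donor_tab <- sort(table(e$label[w]), decreasing = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = e$start[w[1]], end = e$end[w[length(w)]],
        host = host, donor = names(donor_tab)[1],
        n_windows = length(w),
        length = e$end[w[length(w)]] - e$start[w[1]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), host = character(0),
                      donor = character(0), n_windows = integer(0),
                      length = integer(0)))
  do.call(rbind, out)
}

#' Phase subgenomes of a polyploid genome by differential k-mers
#'
#' End-to-end phasing: repetitive k-mer counting, an unevenness
#' prefilter, k-means chromosome assignment, subgenome-specific k-mer
#' selection, window enrichment, and exchange calling. When
#' `exclude_exchanges` is TRUE (one masking iteration), called exchange
#' segments are masked and the specific k-mer sets, enrichment and
#' exchange calls are recomputed, so that exchanged repeats do not
#' contaminate the subgenome-specific sets.
#'
#' @param genome chromosome sequences of the polyploid.
#' @param n_subgenomes expected subgenome count.
#' @param k odd k-mer size.
#' @param min_count minimum genome-wide count for a repetitive k-mer.
#' @param min_fold differential fold threshold between chromosome groups.
#' @param window_size enrichment window (bp).
#' @param alpha FDR threshold for window enrichment.
#' @param min_exchange_windows,max_bridge_windows see [call_exchanges()].
#' @param n_restarts,seed k-means restarts and seed.
#' @param exclude_exchanges recompute specific k-mers after masking
#'   called exchanges.
#' @return object of class `subgenome_partition`: list with `assignment`,
#'   `sets`, `windows`, `exchanges`, `k`, `window_size`, `lengths`.
#' @export
phase_subgenomes <- function(genome, n_subgenomes = 4L, k = 15L,
                             min_count = 10L, min_fold = 2,
                             window_size = 12500L, alpha = 0.05,
                             min_exchange_windows = 5L,
                             max_bridge_windows = 1L,
                             n_restarts = 10L, seed = 1L,
                             exclude_exchanges = TRUE) {
  seqs <- as_seq_vector(genome)
  km <- count_kmers(seqs, k = k, min_total = min_count)
  if (ncol(km$counts) == 0)
    stop("no repetitive k-mers at min_count = ", min_count)
  norm <- normalize_kmer_counts(km)
  uneven <- apply(norm, 2L, function(v) {
    max(v) > min_fold * stats::median(v) + 1e-12
  })
  assignment <- cluster_chromosomes(
    km, n_subgenomes = n_subgenomes, kmers = km$kmers[uneven],
    n_restarts = n_restarts, seed = seed)
  run_pass <- function(seqs_count) {
    # sets are selected from seqs_count (possibly exchange-masked), but
    # enrichment and exchange calls are always evaluated on the original
    # sequences
    kmp <- count_kmers(seqs_count, k = k, min_total = min_count)
    sets <- select_differential_kmers(kmp, groups = assignment,
                                      min_fold = min_fold,
                                      min_count = min_count)
    sets <- sets[vapply(sets, length, integer(1)) > 0]
    win <- window_enrichment(seqs, sets, window_size = window_size,
                             k = k, alpha = alpha)
    exch <- call_exchanges(win, assignment,
                           min_exchange_windows = min_exchange_windows,
                           max_bridge_windows = max_bridge_windows)
    list(sets = sets, windows = win, exchanges = exch)
  }
  pass <- run_pass(seqs)
  if (exclude_exchanges && nrow(pass$exchanges)) {
    masked <- seqs
    for (i in seq_len(nrow(pass$exchanges))) {
      e <- pass$exchanges[i, ]
      substr(masked[[e$chrom]], e$start + 1L, e$end) <-
        strrep("N", e$end - e$start)
    }
    pass <- run_pass(masked)
  }
  structure(list(assignment = assignment, sets = pass$sets,
                 windows = pass$windows, exchanges = pass$exchanges,
                 k = k, window_size = window_size,
                 lengths = nchar(seqs)),
            class = "subgenome_partition")
}

#' @export
print.subgenome_partition <- function(x, ...) {
  cat("Subgenome partition (k =", x$k, ")\n")
  print(table(x$assignment))
  cat("exchange segments called:", nrow(x$exchanges), "\n")
  invisible(x)
}

#' Assign a genomic interval to a subgenome
#'
#' The label of the exchange segment containing the interval midpoint,
#' if any, else the host chromosome's subgenome. Intervals straddling an
#' exchange boundary are resolved by this midpoint rule.
#'
#' @param partition a [phase_subgenomes()] result.
#' @param chrom chromosome name.
#' @param start,end interval (0-based half-open), within the chromosome.
#' @return subgenome label.
#' @export
assign_interval <- function(partition, chrom, start, end) {
  if (!chrom %in% names(partition$assignment))
    stop("unknown chromosome: ", chrom)
  if (start < 0 || end > partition$lengths[[chrom]] || start >= end)
    stop("interval outside chromosome ", chrom)
  mid <- (start + end) / 2
  ex <- partition$exchanges
  if (nrow(ex)) {
    hit <- ex$chrom == chrom & ex$start <= mid & mid < ex$end
    if (any(hit)) return(ex$donor[which(hit)[1]])
  }
  unname(partition$assignment[[chrom]])
}

#' Profile read composition by subgenome-specific k-mers
#'
#' Classifies each read to the subgenome whose specific k-mers it matches
#' most (ties or zero matches leave the read unassigned), places reads on
#' the host genome by their first unique exact k-mer match, and tabulates
#' assigned-read depth per window -- a k-mer analogue of mapping a
#' relative's short reads onto a phased polyploid genome to measure each
#' subgenome's contribution.
#'
#' @param reads data.frame with a `seq` column (e.g. [simulate_reads()])
#'   or character vector of read sequences.
#' @param genome host genome chromosome sequences.
#' @param partition a [phase_subgenomes()] result (supplies the specific
#'   k-mer sets and window size).
#' @return list with `reads` (per-read label and placement) and `depth`
#'   (per window: assigned-read counts per subgenome).
#' @export
read_composition <- function(reads, genome, partition) {
  seqs <- as_seq_vector(genome)
  rd <- if (is.data.frame(reads)) reads$seq else reads
  sets <- partition$sets
  if (!length(sets)) stop("partition has no specific k-mer sets")
  hits <- cpp_classify_reads(rd, partition$k, unname(sets))
  colnames(hits) <- names(sets)
  best <- apply(hits, 1L, which.max)
  bestn <- hits[cbind(seq_len(nrow(hits)), best)]
  tied <- rowSums(hits == bestn) > 1L
  label <- ifelse(bestn == 0L | tied, NA_character_, names(sets)[best])
  loc <- cpp_locate_reads(unname(seqs), rd, partition$k)
  out_reads <- data.frame(
    seq_id = seq_along(rd), label = label,
    chrom = ifelse(is.na(loc[, 1]), NA_character_, names(seqs)[loc[, 1]]),
    pos = loc[, 2], stringsAsFactors = FALSE)
  placed <- out_reads[!is.na(out_reads$label) & !is.na(out_reads$chrom), ]
  ws <- partition$window_size
  depth_rows <- list()
  for (cn in names(seqs)) {
    nw <- ceiling(nchar(seqs[[cn]]) / ws)
    d <- matrix(0L, nw, length(sets), dimnames = list(NULL, names(sets)))
    pc <- placed[placed$chrom == cn, ]
    if (nrow(pc)) {
      w <- pmin(pc$pos %/% ws, nw - 1L) + 1L
      for (s in names(sets)) {
        t1 <- table(w[pc$label == s])
        d[as.integer(names(t1)), s] <- as.integer(t1)
      }
    }
    depth_rows[[cn]] <- cbind(
      data.frame(chrom = cn, window = seq_len(nw) - 1L,
                 start = (seq_len(nw) - 1L) * ws,
                 end = pmin(seq_len(nw) * ws, nchar(seqs[[cn]])),
                 stringsAsFactors = FALSE),
      as.data.frame(d))
  }
  list(reads = out_reads, depth = do.call(rbind, unname(depth_rows)))
}
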