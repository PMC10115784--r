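# Independent oracles and small fixtures used across tests. These are
# deliberately naive implementations kept separate from the package code
# paths they check.

# compact scenario for fast unit tests
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    n_gene_families = 24L, n_single_copy = 4L, chrom_length = 100000L,
    repeats_per_chrom = 20L, ltr_per_chrom = 8L,
    exchanges = default_exchanges(100000L), seed = 1L)
  defaults[names(args)] <- args
  do.call(scenario_spec, defaults)
}

# naive dictionary k-mer recount (canonical strand)
naive_kmer_count <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  out <- new.env(parent = emptyenv())
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    key <- min(w, revcomp(w))
    out[[key]] <- (if (is.null(out[[key]])) 0L else out[[key]]) + 1L
  }
  keys <- sort(ls(out))
  stats::setNames(vapply(keys, function(x) out[[x]], integer(1)), keys)
}

# brute-force maximum monotone chain score over <= 12 homolog pairs,
# enumerating every subset chain in both orientations
brute_best_chain <- function(pairs, match_score = 50, gap_penalty = 1,
                             max_gap_genes = 25L) {
  n <- nrow(pairs)
  best <- -Inf
  best_sets <- list()
  for (orient in c(1, -1)) {
    r1 <- pairs$rank1
    r2 <- orient * pairs$rank2
    score_chain <- function(idx) {
      o <- idx[order(r1[idx])]
      s <- match_score
      for (i in seq_along(o)[-1]) {
        g1 <- r1[o[i]] - r1[o[i - 1]] - 1
        g2 <- r2[o[i]] - r2[o[i - 1]] - 1
        if (r1[o[i]] <= r1[o[i - 1]] || r2[o[i]] <= r2[o[i - 1]] ||
            g1 > max_gap_genes || g2 > max_gap_genes)
          return(-Inf)
        s <- s + match_score - gap_penalty * (g1 + g2)
      }
      s
    }
    for (m in seq_len(2^n - 1)) {
      idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      s <- score_chain(idx)
      if (s > best) {
        best <- s
        best_sets <- list(sort(idx))
      } else if (s == best) {
        best_sets <- c(best_sets, list(sort(idx)))
      }
    }
  }
  list(score = best, sets = unique(best_sets))
}

# independent NG86 implementation: recursive path enumeration written
# differently from the package version
GCo <- Biostrings::GENETIC_CODE
STOPo <- names(GCo)[GCo == "*"]

oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in c("A", "C", "G", "T")) {
      if (b == orig) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (!(mut %in% STOPo) && GCo[[mut]] == GCo[[codon]])
        total <- total + 1
    }
  }
  total / 3
}

oracle_path_diffs <- function(c1, c2) {
  diff_pos <- which(vapply(1:3, function(p)
    substr(c1, p, p) != substr(c2, p, p), logical(1)))
  if (!length(diff_pos)) return(c(0, 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    res <- list()
    for (p in remaining) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (nxt %in% STOPo) next
      syn <- GCo[[cur]] == GCo[[nxt]]
      for (tail in walk(nxt, setdiff(remaining, p)))
        res <- c(res, list(tail + if (syn) c(1, 0) else c(0, 1)))
    }
    res
  }
  paths <- walk(c1, diff_pos)
  if (!length(paths)) {
    # all paths stop-blocked: count through stops, all orders
    walk2 <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0)))
      res <- list()
      for (p in remaining) {
        nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                      substr(cur, p + 1, 3))
        syn <- !(cur %in% STOPo) && !(nxt %in% STOPo) &&
          GCo[[cur]] == GCo[[nxt]]
        for (tail in walk2(nxt, setdiff(remaining, p)))
          res <- c(res, list(tail + if (syn) c(1, 0) else c(0, 1)))
      }
      res
    }
    paths <- walk2(c1, diff_pos)
  }
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(cds1, cds2) {
  sp <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  co1 <- sp(toupper(cds1))
  co2 <- sp(toupper(cds2))
  S <- mean(c(sum(vapply(co1, oracle_syn_sites, numeric(1))),
              sum(vapply(co2, oracle_syn_sites, numeric(1)))))
  N <- 3 * length(co1) - S
  d <- rowSums(mapply(oracle_path_diffs, co1, co2))
  ps <- if (S > 0) d[1] / S else 0
  pn <- if (N > 0) d[2] / N else 0
  # saturation convention: proportions >= 3/4 have no finite JC distance
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# enumerate all rooted binary leaf-labeled trees (nested list form) over
# a label set, by inserting each new leaf on every edge incl. a new root
enumerate_rooted <- function(labels) {
  if (length(labels) == 1) return(list(labels[1]))
  smaller <- enumerate_rooted(labels[-length(labels)])
  leaf <- labels[length(labels)]
  out <- list()
  insert_everywhere <- function(node) {
    res <- list(list(node, leaf)) # above this node
    if (!is.character(node)) {
      for (ci in seq_along(node)) {
        for (sub in insert_everywhere(node[[ci]])) {
          copy <- node
          copy[[ci]] <- sub
          res <- c(res, list(copy))
        }
      }
    }
    res
  }
  for (tr in smaller) out <- c(out, insert_everywhere(tr))
  out
}

nested_to_newick <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(vapply(x, nested_to_newick, character(1)),
                    collapse = ","), ")")
}

# additive distance matrix from a random rooted-then-unrooted tree
random_additive_matrix <- function(n_taxa, seed) {
  tr <- allorigin:::with_seed(seed, ape::rtree(n_taxa,
                                               br = function(n)
                                                 stats::runif(n, 0.1, 1)))
  tr <- ape::unroot(tr)
  list(tree = tr, D = stats::cophenetic(tr))
}
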