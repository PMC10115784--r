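#' @useDynLib allorigin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table setkey
#' @import methods
NULL

.datatable.aware <- TRUE

DNA_BASES_INT <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' functions do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# integer-coded DNA (0=A,1=C,2=G,3=T) <-> character
int_to_dna <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[v + 1L])
}

dna_to_int <- function(s) {
  v <- utf8ToInt(toupper(s))
  out <- match(v, c(65L, 67L, 71L, 84L)) - 1L
  if (anyNA(out)) stop("sequence contains non-ACGT characters")
  out
}

random_seq_int <- function(n) sample.int(4L, n, replace = TRUE) - 1L

#' Jukes-Cantor sequence evolution for an expected substitution load
#'
#' Applies the JC69 transition probability for branch length `d`
#' (expected substitutions per site): each site changes with probability
#' 3/4 (1 - exp(-4 d / 3)), to a uniformly chosen different base.
#' @noRd
evolve_jc <- function(seq, d) {
  if (d <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  idx <- which(stats::runif(length(seq)) < p)
  if (length(idx))
    seq[idx] <- (seq[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  seq
}

# Random codon sequence free of stop codons, length n_codons * 3.
random_cds_int <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  repeat_draw <- function(n) {
    m <- matrix(sample.int(4L, 3L * n, replace = TRUE) - 1L, nrow = 3L)
    bad <- apply(m, 2L, function(cd) {
      int_to_dna(cd) %in% stops
    })
    list(m = m, bad = bad)
  }
  d <- repeat_draw(n_codons)
  while (any(d$bad)) {
    r <- repeat_draw(sum(d$bad))
    d$m[, d$bad] <- r$m
    d$bad[d$bad] <- r$bad
  }
  as.integer(d$m)
}

# Sample n non-overlapping intervals of width w in [0, L), avoiding
# `occupied` (matrix with columns start, end; 0-based half-open).
place_intervals <- function(n, w, L, occupied = NULL, max_tries = 200L) {
  starts <- integer(0)
  occ_s <- if (is.null(occupied)) integer(0) else occupied[, 1L]
  occ_e <- if (is.null(occupied)) integer(0) else occupied[, 2L]
  tries <- 0L
  while (length(starts) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- sort(sample.int(L - w, n - length(starts)) - 1L)
    for (s in cand) {
      e <- s + w
      if (!any(s < occ_e & e > occ_s)) {
        starts <- c(starts, s)
        occ_s <- c(occ_s, s)
        occ_e <- c(occ_e, e)
      }
    }
  }
  if (length(starts) < n)
    stop("could not place ", n, " intervals of width ", w,
         " on a sequence of length ", L, "; reduce feature density")
  sort(starts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
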