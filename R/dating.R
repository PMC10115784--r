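# Molecular dating: LTR terminal-repeat divergence -> insertion ages and
# divergence-hybridization windows; NG86 Ka/Ks -> Ks-ratio divergence
# dating against a calibrated species split.

#' Date an LTR retrotransposon insertion from its terminal repeats
#'
#' The two long terminal repeats of an element are identical at
#' insertion; their Jukes-Cantor corrected divergence K dates the
#' insertion as T = K / (2 mu). The repeats are globally aligned and the
#' mismatch fraction p is taken over aligned non-gap sites.
#'
#' @param ltr5,ltr3 the 5' and 3' terminal repeat sequences.
#' @param mu substitution rate in substitutions/site/year (no default: a
#'   rate must be chosen explicitly for the organism at hand).
#' @return list with `p` (raw mismatch fraction), `K` (JC divergence) and
#'   `T` (insertion age, MY); `K` and `T` are NA with a warning when
#'   p >= 0.75 (saturated; element should be excluded).
#' @export
ltr_insertion_age <- function(ltr5, ltr3, mu) {
  if (nchar(ltr5) == 0 || nchar(ltr3) == 0) stop("empty LTR sequence")
  if (missing(mu) || is.null(mu)) stop("mu (subs/site/year) is required")
  if (nchar(ltr5) == nchar(ltr3)) {
    a <- strsplit(toupper(ltr5), "")[[1]]
    b <- strsplit(toupper(ltr3), "")[[1]]
  } else {
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ltr5),
                                        Biostrings::DNAString(ltr3),
                                        type = "global")
    a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  }
  ok <- a != "-" & b != "-"
  p <- sum(a[ok] != b[ok]) / sum(ok)
  if (p >= 0.75) {
    warning("LTR pair saturated (p >= 0.75); age undefined")
    return(list(p = p, K = NA_real_, T = NA_real_))
  }
  K <- -0.75 * log(1 - 4 * p / 3)
  list(p = p, K = K, T = K / (2 * mu) / 1e6)
}

#' Insertion ages for annotated LTR elements
#'
#' Extracts both terminal repeats of each annotated element from the
#' genome and dates it with [ltr_insertion_age()]. Detection of elements
#' is out of scope: elements enter via annotation (simulator truth or a
#' user table).
#'
#' @param genome chromosome sequences.
#' @param ltr_table data.frame with columns `chrom`, `start`, `end`
#'   (element bounds, 0-based half-open) and optionally `host`,
#'   `exchanged`.
#' @param ltr_length terminal repeat length in bp.
#' @param mu substitutions/site/year.
#' @return `ltr_table` with added columns `p`, `K`, `age_est` (MY).
#' @export
ltr_insertion_ages <- function(genome, ltr_table, ltr_length, mu) {
  seqs <- as_seq_vector(genome)
  res <- vapply(seq_len(nrow(ltr_table)), function(i) {
    cn <- ltr_table$chrom[i]
    s0 <- ltr_table$start[i]
    e0 <- ltr_table$end[i]
    l5 <- substring(seqs[[cn]], s0 + 1L, s0 + ltr_length)
    l3 <- substring(seqs[[cn]], e0 - ltr_length + 1L, e0)
    r <- suppressWarnings(ltr_insertion_age(l5, l3, mu))
    c(r$p, r$K, r$T)
  }, numeric(3))
  out <- ltr_table
  out$p <- res[1, ]
  out$K <- res[2, ]
  out$age_est <- res[3, ]
  out
}

#' Divergence-to-hybridization window from LTR insertion ages
#'
#' Symmetric percentile confidence interval (default 95%: the 2.5% and
#' 97.5% quantiles) of the subgenome-specific LTR insertion ages; the
#' bounds estimate the start (divergence) and end (hybridization) of a
#' subgenome's independent evolution. Elements flagged as exchanged must
#' be excluded by the caller or via the `exclude` argument.
#'
#' @param ages named list of numeric age vectors (MY), one per subgenome,
#'   or a data.frame with columns `host` and `age_est`.
#' @param percentile central interval mass (percent).
#' @param exclude optional logical vector (same length as the data.frame
#'   rows) marking elements to drop, e.g. `exchanged` flags.
#' @param min_elements minimum elements required per subgenome.
#' @return data.frame with columns `subgenome`, `n`, `lower`, `upper`
#'   (MY).
#' @export
divergence_hybridization_window <- function(ages, percentile = 95,
                                            exclude = NULL,
                                            min_elements = 20L) {
  if (is.data.frame(ages)) {
    if (!is.null(exclude)) ages <- ages[!exclude, ]
    ages <- split(ages$age_est, ages$host)
  }
  ages <- lapply(ages, function(a) a[is.finite(a)])
  lo_q <- (100 - percentile) / 200
  rows <- lapply(names(ages), function(s) {
    a <- ages[[s]]
    if (length(a) < min_elements)
      stop("too few LTR elements for subgenome ", s, " (", length(a),
           " < ", min_elements, ")")
    q <- stats::quantile(a, c(lo_q, 1 - lo_q), names = FALSE, type = 7)
    data.frame(subgenome = s, n = length(a), lower = q[1], upper = q[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- NG86 Ka/Ks -------------------------------------------------------------

GC <- Biostrings::GENETIC_CODE
STOPS <- names(GC)[GC == "*"]
NTS <- c("A", "C", "G", "T")

codon_split <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# synonymous site count of one codon (0..3): per position, the fraction
# of the three possible changes that are synonymous; changes to stop
# codons count as nonsynonymous.
codon_syn_sites <- function(codon) {
  aa <- GC[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(NTS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!alt %in% STOPS && GC[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts between two codons over all
# mutational paths; paths through stop codons are excluded unless all
# paths are blocked.
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    pm <- list()
    idx <- seq_len(nd)
    gen <- function(prefix, rest) {
      if (!length(rest)) {
        pm[[length(pm) + 1L]] <<- pos[prefix]
        return(invisible())
      }
      for (r in seq_along(rest)) gen(c(prefix, rest[r]), rest[-r])
    }
    gen(integer(0), idx)
    pm
  }
  score_path <- function(order) {
    cur <- c1
    sd <- 0
    ndc <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOPS) return(NULL)
      if (GC[[cur]] == GC[[nxt]]) sd <- sd + 1 else ndc <- ndc + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndc)
  }
  scored <- Filter(Negate(is.null), lapply(perms, score_path))
  if (!length(scored)) {
    # all paths blocked by stops: fall back to counting through them
    scored <- lapply(perms, function(order) {
      cur <- c1
      sd <- 0
      ndc <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        same <- !cur %in% STOPS && !nxt %in% STOPS && GC[[cur]] == GC[[nxt]]
        if (same) sd <- sd + 1 else ndc <- ndc + 1
        cur <- nxt
      }
      c(sd = sd, nd = ndc)
    })
  }
  colMeans(do.call(rbind, scored))
}

#' Ka and Ks by the Nei-Gojobori (NG86) method
#'
#' Synonymous and nonsynonymous site fractions are counted per codon and
#' averaged over the two sequences; observed differences are averaged
#' over all mutational paths between differing codons (paths through
#' stop codons excluded); the proportions ps and pn are Jukes-Cantor
#' corrected to Ks and Ka.
#'
#' @param cds1,cds2 aligned CDS sequences of equal length (gaps `---`
#'   allowed in whole codons; gapped codon columns are skipped).
#' @return list with `S`, `N` (site counts), `Sd`, `Nd` (differences),
#'   `ps`, `pn`, `Ks`, `Ka`, `n_codons`.
#' @export
ng86_ka_ks <- function(cds1, cds2) {
  cds1 <- toupper(cds1)
  cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2))
    stop("aligned CDS must have equal length")
  co1 <- codon_split(cds1)
  co2 <- codon_split(cds2)
  ok <- !grepl("-", co1) & !grepl("-", co2)
  co1 <- co1[ok]
  co2 <- co2[ok]
  stop1 <- which(co1 %in% STOPS)
  stop2 <- which(co2 %in% STOPS)
  if (length(stop1) || length(stop2))
    stop("internal stop codon at codon index ",
         min(c(stop1, stop2)))
  S <- (sum(vapply(co1, codon_syn_sites, numeric(1))) +
          sum(vapply(co2, codon_syn_sites, numeric(1)))) / 2
  N <- 3 * length(co1) - S
  diffs <- mapply(codon_path_diffs, co1, co2)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) {
      warning("proportion >= 0.75; distance saturated (NA)")
      return(NA_real_)
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn), n_codons = length(co1))
}

#' Ks between homologous gene copies, stop codons masked
#'
#' Pairwise-deletion convenience wrapper: codon columns containing a
#' stop codon in either sequence (which arise under unconstrained
#' simulated evolution) are masked before [ng86_ka_ks()].
#'
#' @param cds1,cds2 equal-length CDS sequences.
#' @return the [ng86_ka_ks()] record.
#' @export
ks_pairwise <- function(cds1, cds2) {
  co1 <- codon_split(toupper(cds1))
  co2 <- codon_split(toupper(cds2))
  bad <- co1 %in% STOPS | co2 %in% STOPS
  ng86_ka_ks(paste(co1[!bad], collapse = ""),
             paste(co2[!bad], collapse = ""))
}

#' Per-family Ks between two genome copies of a simulated complex
#'
#' @param sim a `polyploid_sim`.
#' @param leaf1,leaf2 genome-copy labels (e.g. `"tet_A"`, `"out"`).
#' @return numeric vector of Ks values, one per shared gene family.
#' @export
ks_between_copies <- function(sim, leaf1, leaf2) {
  g <- sim$genes
  g1 <- g[g$leaf == leaf1, ]
  g2 <- g[g$leaf == leaf2, ]
  fams <- intersect(g1$family, g2$family)
  vapply(fams, function(f) {
    suppressWarnings(ks_pairwise(g1$cds[g1$family == f][1],
                                 g2$cds[g2$family == f][1])$Ks)
  }, numeric(1))
}

#' Ks-ratio divergence dating against a calibrated split
#'
#' Under rate constancy, divergence time scales linearly with Ks:
#' `T = median_ks_query / median_ks_calibration * t_calibration`. The
#' default calibration time of 7.7 MY corresponds to a well-dated
#' outgroup speciation used as reference.
#'
#' @param median_ks_query median Ks of the lineage pair to date.
#' @param median_ks_calibration median Ks of the calibration pair (> 0).
#' @param t_calibration calibration divergence time (MY).
#' @return estimated divergence time (MY).
#' @export
ks_ratio_dating <- function(median_ks_query, median_ks_calibration,
                            t_calibration = 7.7) {
  if (!is.finite(median_ks_calibration) || median_ks_calibration <= 0)
    stop("calibration median Ks must be positive")
  median_ks_query / median_ks_calibration * t_calibration
}

#' Histogram peaks of a Ks distribution
#'
#' Bins Ks values on `[0, cap]` and reports local maxima whose height is
#' at least `min_prominence` of the tallest bin; used to screen for
#' recent whole-genome duplication signatures (a paralog peak below the
#' speciation peak). An empty input reports no peaks.
#'
#' @param ks numeric Ks values.
#' @param bin_width histogram bin width.
#' @param cap upper bound of the histogram.
#' @param min_prominence minimum peak height as a fraction of the
#'   tallest bin.
#' @return list with `breaks`, `counts`, `peaks` (data.frame `ks`,
#'   `count`) and `has_peak`.
#' @export
ks_distribution_peaks <- function(ks, bin_width = 0.01, cap = NULL,
                                  min_prominence = 0.25) {
  ks <- ks[is.finite(ks) & ks >= 0]
  if (length(ks) == 0)
    return(list(breaks = numeric(0), counts = integer(0),
                peaks = data.frame(ks = numeric(0), count = integer(0)),
                has_peak = FALSE))
  if (length(ks) < 50)
    warning("fewer than 50 Ks values; peak calls will be unstable")
  if (is.null(cap)) cap <- max(ks) + bin_width
  breaks <- seq(0, cap + bin_width, by = bin_width)
  h <- graphics::hist(pmin(ks, cap), breaks = breaks, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  is_peak <- vapply(seq_along(cnt), function(i) {
    left <- if (i == 1) 0L else cnt[i - 1]
    right <- if (i == length(cnt)) 0L else cnt[i + 1]
    cnt[i] > left && cnt[i] >= right &&
      cnt[i] >= min_prominence * max(cnt)
  }, logical(1))
  peaks <- data.frame(ks = mids[is_peak], count = cnt[is_peak])
  list(breaks = h$breaks, counts = cnt, peaks = peaks,
       has_peak = nrow(peaks) > 0)
}
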