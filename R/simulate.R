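#' Simulate a polyploid genome complex with known evolutionary truth
#'
#' Generates a diploid outgroup, an allotetraploid (subgenomes A and C)
#' and an allo-octoploid (subgenomes A--D) -- or their autopolyploid
#' counterparts -- from a [scenario_spec()]. Sequences evolve under a
#' Jukes-Cantor model at `subst_rate` substitutions/site/MY along the
#' scenario's lineage tree. Gene families are planted collinearly at a
#' 1:2:4 copy ratio (outgroup : tetraploid : octoploid), subgenome-specific
#' repeat motifs and LTR retrotransposons are inserted during each
#' subgenome's divergence-to-hybridization window, and homoeologous
#' exchanges copy donor segments (backbone, repeats, LTR elements and gene
#' copies) onto recipient chromosomes at the stated exchange time, after
#' which both copies continue to diverge independently.
#'
#' The two terminal repeats of an LTR element are identical at insertion
#' and subsequently mutate independently, so their divergence dates the
#' insertion (T = K / 2 mu).
#'
#' @param spec a [scenario_spec()].
#' @return An object of class `polyploid_sim`: a list with elements
#'   `spec`, `roles` (genome copy -> census role), `chrom_table`,
#'   `genomes` (per-species [Biostrings::DNAStringSet]), `genes`
#'   (data.frame incl. CDS, 0-based half-open coordinates), `repeats`,
#'   `ltrs` (incl. true insertion ages in MY and exchange flags),
#'   `exchanges` (planted truth) and `divergence` (true pairwise MRCA
#'   ages between genome copies).
#' @examples
#' sim <- simulate_scenario(scenario_spec(n_gene_families = 12,
#'   n_single_copy = 2, chrom_length = 1e5, repeats_per_chrom = 10,
#'   ltr_per_chrom = 4, exchanges = NULL, seed = 7))
#' sim$chrom_table$chrom
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_scenario(spec)
  with_seed(spec$seed, simulate_scenario_impl(spec))
}

simulate_scenario_impl <- function(spec) {
  rate <- spec$subst_rate
  tree <- guide_tree(spec)
  meta <- leaf_meta()
  L <- spec$chrom_length
  ngrp <- spec$n_chromosomes
  div <- divergence_times(tree)

  # per-subgenome sequence templates
  subs <- c("A", "B", "C", "D", "O")
  motifs <- lapply(stats::setNames(subs, subs),
                   function(s) random_seq_int(spec$repeat_length))
  ltr_tmpl <- lapply(stats::setNames(subs, subs),
                     function(s) random_seq_int(spec$ltr_length))
  ltr_int_tmpl <- lapply(stats::setNames(subs, subs),
                         function(s) random_seq_int(spec$ltr_internal_length))
  windows <- spec$windows
  windows$O <- c(1, spec$t_root) # outgroup repeats: uninformative filler

  # family bookkeeping: 1:2:4 families then single-copy families
  n_fam <- spec$n_gene_families
  n_single <- spec$n_single_copy
  fam_ids <- seq_len(n_fam + n_single)
  fam_single <- fam_ids > n_fam
  fam_group <- sample(rep(seq_len(ngrp), length.out = length(fam_ids)))
  all_leaves <- meta$leaf
  single_leaves <- c("out", "tet_A", "oct_A")

  exch <- spec$exchanges
  ltr_elem_len <- 2L * spec$ltr_length + spec$ltr_internal_length

  chrom_rows <- list()
  gene_rows <- list()
  repeat_rows <- list()
  ltr_rows <- list()
  exch_rows <- list()
  chrom_seqs <- list()

  for (g in seq_len(ngrp)) {
    exch_g <- if (is.null(exch)) NULL else exch[exch$chrom == g, , drop = FALSE]
    forbidden <- NULL
    if (!is.null(exch_g) && nrow(exch_g)) {
      b <- sort(unique(c(exch_g$start, exch_g$end)))
      forbidden <- cbind(b, b + 1L)
    }

    # collinear gene slots, shared across all genome copies in the group
    fams_g <- fam_ids[fam_group == g]
    fams_g <- sample(fams_g) # random gene order along the chromosome
    slot_start <- place_intervals(length(fams_g), spec$gene_length, L,
                                  occupied = forbidden)
    gene_occ <- cbind(slot_start, slot_start + spec$gene_length)

    # backbone evolution down the guide tree
    bb <- evolve_guide(random_seq_int(L), tree, rate)

    # per-leaf repeat and LTR annotations
    ann <- list()
    for (li in seq_len(nrow(meta))) {
      leaf <- meta$leaf[li]
      sub <- meta$subgenome[li]
      occ <- rbind(gene_occ, forbidden)
      rst <- place_intervals(spec$repeats_per_chrom, spec$repeat_length, L,
                             occupied = occ)
      occ <- rbind(occ, cbind(rst, rst + spec$repeat_length))
      lst <- place_intervals(spec$ltr_per_chrom, ltr_elem_len, L,
                             occupied = occ)
      w <- windows[[sub]]
      rep_sub <- rep(sub, spec$repeats_per_chrom)
      if (spec$repeat_contamination > 0 && sub != "O") {
        flip <- stats::runif(spec$repeats_per_chrom) < spec$repeat_contamination
        others <- setdiff(c("A", "B", "C", "D"), sub)
        rep_sub[flip] <- sample(others, sum(flip), replace = TRUE)
      }
      ann[[leaf]] <- list(
        repeats = data.frame(start = rst, end = rst + spec$repeat_length,
                             age = stats::runif(spec$repeats_per_chrom,
                                                w[1], w[2]),
                             motif = rep_sub, stringsAsFactors = FALSE),
        ltrs = data.frame(start = lst, end = lst + ltr_elem_len,
                          age = stats::runif(spec$ltr_per_chrom, w[1], w[2]),
                          stringsAsFactors = FALSE))
    }

    # gene family sequences down the guide tree
    fam_seqs <- list() # fam_seqs[[as.character(fam)]][[leaf]] = int cds
    fam_parents <- list()
    for (f in fams_g) {
      ev <- evolve_guide(random_cds_int(spec$gene_length %/% 3L), tree, rate)
      pres <- if (fam_single[f]) single_leaves else all_leaves
      if (!is.null(spec$copy_loss)) {
        drop <- spec$copy_loss$leaf[spec$copy_loss$family == f]
        pres <- setdiff(pres, drop)
      }
      fam_seqs[[as.character(f)]] <- ev$leaves[pres]
      fam_parents[[as.character(f)]] <- ev$parents
    }
    fam_slot <- stats::setNames(slot_start, as.character(fams_g))
    fam_origin <- list() # overrides: fam -> leaf -> origin subgenome

    # exchange surgery on gene copies: recipient copy re-branched from the
    # donor lineage at the exchange time; donor copy re-branched likewise
    # so that both descend from the same sequence at t_ex.
    if (!is.null(exch_g) && nrow(exch_g)) {
      for (i in seq_len(nrow(exch_g))) {
        e <- exch_g[i, ]
        dleaf <- paste0("oct_", e$donor)
        rleaf <- paste0("oct_", e$recipient)
        for (f in fams_g) {
          s0 <- fam_slot[[as.character(f)]]
          if (s0 >= e$start && (s0 + spec$gene_length) <= e$end) {
            fs <- fam_seqs[[as.character(f)]]
            if (!(dleaf %in% names(fs)) || !(rleaf %in% names(fs))) next
            par <- fam_parents[[as.character(f)]][[dleaf]]
            at_tex <- evolve_jc(par$seq, rate * (par$age - e$time))
            fs[[dleaf]] <- evolve_jc(at_tex, rate * e$time)
            fs[[rleaf]] <- evolve_jc(at_tex, rate * e$time)
            fam_seqs[[as.character(f)]] <- fs
            fam_origin[[as.character(f)]][[rleaf]] <- e$donor
          }
        }
      }
    }

    # assemble chromosomes
    for (li in seq_len(nrow(meta))) {
      leaf <- meta$leaf[li]
      sub <- meta$subgenome[li]
      cname <- paste0(leaf, "_chr", g)
      seq <- bb$leaves[[leaf]]
      a <- ann[[leaf]]
      for (j in seq_len(nrow(a$repeats))) {
        r <- a$repeats[j, ]
        seq[(r$start + 1L):r$end] <-
          evolve_jc(motifs[[r$motif]], rate * r$age)
      }
      for (j in seq_len(nrow(a$ltrs))) {
        l <- a$ltrs[j, ]
        el <- c(evolve_jc(ltr_tmpl[[sub]], rate * l$age),
                evolve_jc(ltr_int_tmpl[[sub]], rate * l$age),
                evolve_jc(ltr_tmpl[[sub]], rate * l$age))
        seq[(l$start + 1L):l$end] <- el
      }
      for (f in fams_g) {
        fs <- fam_seqs[[as.character(f)]]
        if (!(leaf %in% names(fs))) next
        s0 <- fam_slot[[as.character(f)]]
        seq[(s0 + 1L):(s0 + spec$gene_length)] <- fs[[leaf]]
      }
      chrom_seqs[[cname]] <- seq
      chrom_rows[[cname]] <- data.frame(
        chrom = cname, species = meta$species[li], subgenome = sub,
        leaf = leaf, group = g, length = L, stringsAsFactors = FALSE)
      a$repeats$chrom <- cname
      a$repeats$host <- sub
      a$ltrs$chrom <- cname
      a$ltrs$host <- sub
      a$ltrs$origin <- sub
      a$ltrs$exchanged <- FALSE
      ann[[leaf]] <- a
    }

    # exchange surgery on chromosome segments
    if (!is.null(exch_g) && nrow(exch_g)) {
      for (i in seq_len(nrow(exch_g))) {
        e <- exch_g[i, ]
        dleaf <- paste0("oct_", e$donor)
        rleaf <- paste0("oct_", e$recipient)
        dname <- paste0(dleaf, "_chr", g)
        rname <- paste0(rleaf, "_chr", g)
        idx <- (e$start + 1L):e$end
        par <- bb$parents[[dleaf]]
        at_tex <- evolve_jc(par$seq[idx], rate * (par$age - e$time))
        seg_d <- evolve_jc(at_tex, rate * e$time)
        seg_r <- evolve_jc(at_tex, rate * e$time)
        # overlay donor features inside the interval (shared to t_ex, then
        # independent on the two copies)
        ad <- ann[[dleaf]]
        in_rep <- which(ad$repeats$start >= e$start & ad$repeats$end <= e$end)
        for (j in in_rep) {
          r <- ad$repeats[j, ]
          base <- evolve_jc(motifs[[r$motif]], rate * (r$age - e$time))
          rel <- (r$start - e$start + 1L):(r$end - e$start)
          seg_d[rel] <- evolve_jc(base, rate * e$time)
          seg_r[rel] <- evolve_jc(base, rate * e$time)
          repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
            chrom = rname, start = r$start, end = r$end, motif = r$motif,
            age = r$age, host = e$recipient, stringsAsFactors = FALSE)
        }
        in_ltr <- which(ad$ltrs$start >= e$start & ad$ltrs$end <= e$end)
        for (j in in_ltr) {
          l <- ad$ltrs[j, ]
          b5 <- evolve_jc(ltr_tmpl[[e$donor]], rate * (l$age - e$time))
          b3 <- evolve_jc(ltr_tmpl[[e$donor]], rate * (l$age - e$time))
          bi <- evolve_jc(ltr_int_tmpl[[e$donor]], rate * (l$age - e$time))
          rel0 <- l$start - e$start
          mk <- function() c(evolve_jc(b5, rate * e$time),
                             evolve_jc(bi, rate * e$time),
                             evolve_jc(b3, rate * e$time))
          seg_d[(rel0 + 1L):(rel0 + ltr_elem_len)] <- mk()
          seg_r[(rel0 + 1L):(rel0 + ltr_elem_len)] <- mk()
          ltr_rows[[length(ltr_rows) + 1L]] <- data.frame(
            chrom = rname, start = l$start, end = l$end, age = l$age,
            host = e$recipient, origin = e$donor, exchanged = TRUE,
            stringsAsFactors = FALSE)
        }
        # gene copies (already re-branched above)
        for (f in fams_g) {
          s0 <- fam_slot[[as.character(f)]]
          if (!(s0 >= e$start && (s0 + spec$gene_length) <= e$end)) next
          fs <- fam_seqs[[as.character(f)]]
          rel <- (s0 - e$start + 1L):(s0 - e$start + spec$gene_length)
          if (dleaf %in% names(fs)) seg_d[rel] <- fs[[dleaf]]
          if (rleaf %in% names(fs)) seg_r[rel] <- fs[[rleaf]]
        }
        chrom_seqs[[dname]][idx] <- seg_d
        chrom_seqs[[rname]][idx] <- seg_r
        # recipient's own features inside the interval were overwritten
        ar <- ann[[rleaf]]
        ar$repeats <- ar$repeats[!(ar$repeats$start >= e$start &
                                     ar$repeats$end <= e$end), , drop = FALSE]
        drop_l <- ar$ltrs$start >= e$start & ar$ltrs$end <= e$end
        ar$ltrs <- ar$ltrs[!drop_l, , drop = FALSE]
        ann[[rleaf]] <- ar
        exch_rows[[length(exch_rows) + 1L]] <- data.frame(
          chrom = rname, start = e$start, end = e$end, donor = e$donor,
          recipient = e$recipient, time = e$time, group = g,
          stringsAsFactors = FALSE)
      }
    }

    # truth rows for retained host features and genes
    for (li in seq_len(nrow(meta))) {
      leaf <- meta$leaf[li]
      a <- ann[[leaf]]
      if (nrow(a$repeats))
        repeat_rows[[length(repeat_rows) + 1L]] <-
          a$repeats[, c("chrom", "start", "end", "motif", "age", "host")]
      if (nrow(a$ltrs))
        ltr_rows[[length(ltr_rows) + 1L]] <-
          a$ltrs[, c("chrom", "start", "end", "age", "host", "origin",
                     "exchanged")]
      cname <- paste0(leaf, "_chr", g)
      for (f in fams_g) {
        fs <- fam_seqs[[as.character(f)]]
        if (!(leaf %in% names(fs))) next
        s0 <- fam_slot[[as.character(f)]]
        orig <- fam_origin[[as.character(f)]][[leaf]] %||% meta$subgenome[li]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene = paste0("fam", f, "_", leaf), family = f,
          single_copy = fam_single[f],
          genome = meta$species[li], subgenome = meta$subgenome[li],
          origin = orig, leaf = leaf, chrom = cname,
          start = s0, end = s0 + spec$gene_length,
          cds = int_to_dna(fs[[leaf]]), stringsAsFactors = FALSE)
      }
    }
  }

  chrom_table <- do.call(rbind, unname(chrom_rows))
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$rank <- stats::ave(genes$start, genes$chrom,
                           FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL

  seqs_chr <- vapply(chrom_seqs, int_to_dna, character(1))
  genomes <- lapply(split(chrom_table$chrom, chrom_table$species),
                    function(cn) {
                      Biostrings::DNAStringSet(seqs_chr[cn])
                    })

  structure(list(
    spec = spec, roles = default_roles(), chrom_table = chrom_table,
    genomes = genomes, genes = genes,
    repeats = do.call(rbind, repeat_rows),
    ltrs = do.call(rbind, ltr_rows),
    exchanges = if (length(exch_rows)) do.call(rbind, exch_rows) else NULL,
    divergence = div, motifs = lapply(motifs, int_to_dna)),
    class = "polyploid_sim")
}

#' @export
print.polyploid_sim <- function(x, ...) {
  cat("Simulated polyploid complex (", x$spec$model, " model, seed ",
      x$spec$seed, ")\n", sep = "")
  cat("  chromosomes:", nrow(x$chrom_table), " genes:", nrow(x$genes),
      " LTR elements:", nrow(x$ltrs), "\n")
  cat("  planted exchanges:",
      if (is.null(x$exchanges)) 0L else nrow(x$exchanges), "\n")
  invisible(x)
}

#' Simulate uniform shotgun reads with truth labels
#'
#' Draws single-end reads uniformly over the given genome. The total read
#' count is Poisson with mean `coverage * genome_length / read_length`;
#' each read records its true source chromosome, position, strand and
#' subgenome.
#'
#' @param genome a `polyploid_sim` (with `species` selecting the genome),
#'   a named character vector, or a [Biostrings::DNAStringSet].
#' @param species which simulated species to sequence when `genome` is a
#'   `polyploid_sim`.
#' @param read_length read length in bp.
#' @param coverage expected fold-coverage (> 0).
#' @param seed integer seed; fixes the read set exactly.
#' @return data.frame with columns `id`, `seq`, `chrom`, `pos` (0-based),
#'   `strand`, `subgenome`.
#' @export
simulate_reads <- function(genome, species = "tet", read_length = 100L,
                           coverage = 5, seed = 1L) {
  if (coverage <= 0) stop("coverage must be > 0")
  labels <- NULL
  if (inherits(genome, "polyploid_sim")) {
    ct <- genome$chrom_table
    seqs <- as.character(genome$genomes[[species]])
    labels <- stats::setNames(ct$subgenome, ct$chrom)[names(seqs)]
  } else if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else {
    seqs <- genome
  }
  lens <- nchar(seqs)
  if (any(read_length > lens))
    stop("read_length exceeds the length of chromosome ",
         names(seqs)[which.max(read_length > lens)])
  if (is.null(labels)) labels <- rep(NA_character_, length(seqs))
  with_seed(seed, {
    n <- stats::rpois(1L, coverage * sum(lens) / read_length)
    ci <- sample.int(length(seqs), n, replace = TRUE,
                     prob = lens - read_length + 1)
    pos <- floor(stats::runif(n) * (lens[ci] - read_length + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rd <- substring(seqs[ci], pos + 1, pos + read_length)
    rc <- strand == "-"
    if (any(rc))
      rd[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rd[rc])))
    data.frame(id = sprintf("read%06d", seq_len(n)), seq = unname(rd),
               chrom = names(seqs)[ci], pos = as.integer(pos),
               strand = strand, subgenome = unname(labels[ci]),
               stringsAsFactors = FALSE)
  })
}
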