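#' Parameterize a polyploidization simulation scenario
#'
#' A scenario describes a diploid outgroup plus four diverged progenitor
#' subgenomes (A, B, C, D), two allotetraploidization events (AC and BD),
#' and one allooctoploidization (AC x BD), together with substitution
#' rates, chromosome layout, gene families planted at a 1:2:4 copy ratio
#' across outgroup:tetraploid:octoploid, subgenome-specific repeat and
#' LTR retrotransposon bursts during each subgenome's
#' divergence-to-hybridization window, and homoeologous exchanges.
#'
#' Two lineage models are supported. Under `model = "reticulate"` the
#' octoploid carries four subgenomes contributed by distinct progenitors,
#' so the expected rooted gene-tree shape pairs each tetraploid copy with
#' one octoploid copy. Under `model = "autopolyploid"` the octoploid arose
#' by a nested whole-genome duplication within the tetraploid's sister
#' lineage, so each tetraploid copy is expected to be sister to a cherry
#' of two octoploid copies.
#'
#' All times are in million years (MY); `subst_rate` is substitutions per
#' site per MY. Chromosome coordinates are 0-based half-open internally.
#'
#' @param model `"reticulate"` or `"autopolyploid"`.
#' @param t_ab,t_abc,t_do,t_root progenitor divergence ages (MY): A-B
#'   split, AB-C split, D-outgroup split, and the root (ABC vs D/outgroup).
#' @param t_hyb_ac,t_hyb_bd allotetraploid formation times for AC and BD.
#' @param t_tet_oct split of the tetraploid species from the AC stock that
#'   later entered the octoploid.
#' @param t_oct allooctoploid (AC x BD) formation time.
#' @param t_wgd1,t_speciation,t_wgd2 node ages used only by the
#'   autopolyploid model: first duplication, tetraploid/octoploid
#'   speciation, and the second (lineage-specific) duplication.
#' @param subst_rate substitutions/site/MY (Jukes-Cantor).
#' @param n_chromosomes chromosomes per subgenome (= homoeologous groups).
#' @param chrom_length chromosome length in bp.
#' @param n_gene_families gene families planted at the 1:2:4 ratio.
#' @param n_single_copy extra families planted once per species.
#' @param gene_length CDS length in bp (multiple of 3).
#' @param repeat_length,repeats_per_chrom subgenome-specific repeat motif
#'   length and copy number per chromosome.
#' @param repeat_contamination fraction of repeat copies planted with the
#'   motif of a *different* subgenome (phasing noise).
#' @param ltr_per_chrom,ltr_length,ltr_internal_length LTR-RT elements per
#'   chromosome, terminal-repeat length and internal-domain length.
#' @param windows named list (A, B, C, D) of `c(lower, upper)` insertion
#'   windows (MY) for subgenome-specific repeats and LTR-RTs.
#' @param exchanges `NULL` or a data.frame with columns `donor`,
#'   `recipient` (subgenome letters), `chrom` (homoeologous group index),
#'   `start`, `end` (bp, 0-based half-open) and `time` (MY). Use
#'   [default_exchanges()] for the standard planting.
#' @param copy_loss `NULL` or a data.frame with columns `family` (index)
#'   and `leaf` (genome copy, e.g. `"oct_B"`) naming copies to delete.
#' @param seed integer; fully determines the simulation output.
#' @return An object of class `scenario_spec`.
#' @seealso [simulate_scenario()], [default_exchanges()]
#' @export
scenario_spec <- function(model = c("reticulate", "autopolyploid"),
                          t_ab = 4.7, t_abc = 5.5, t_do = 7.3, t_root = 7.7,
                          t_hyb_ac = 0.7, t_hyb_bd = 0.91,
                          t_tet_oct = 0.66, t_oct = 0.44,
                          t_wgd1 = 7.2, t_speciation = 5.0, t_wgd2 = 4.0,
                          subst_rate = 0.005,
                          n_chromosomes = 3L, chrom_length = 5e5,
                          n_gene_families = 200L, n_single_copy = 30L,
                          gene_length = 900L,
                          repeat_length = 250L, repeats_per_chrom = 60L,
                          repeat_contamination = 0,
                          ltr_per_chrom = 20L, ltr_length = 200L,
                          ltr_internal_length = 400L,
                          windows = NULL,
                          exchanges = default_exchanges(chrom_length),
                          copy_loss = NULL,
                          seed = 1L) {
  model <- match.arg(model)
  if (is.null(windows)) {
    windows <- if (model == "reticulate") {
      list(A = c(t_hyb_ac, t_ab), B = c(t_hyb_bd, t_do),
           C = c(t_hyb_ac, t_abc), D = c(t_hyb_bd, t_do))
    } else {
      list(A = c(1.0, t_wgd2), B = c(1.0, t_wgd2),
           C = c(1.0, t_wgd2), D = c(1.0, t_wgd2))
    }
  }
  spec <- structure(list(
    model = model,
    t_ab = t_ab, t_abc = t_abc, t_do = t_do, t_root = t_root,
    t_hyb_ac = t_hyb_ac, t_hyb_bd = t_hyb_bd,
    t_tet_oct = t_tet_oct, t_oct = t_oct,
    t_wgd1 = t_wgd1, t_speciation = t_speciation, t_wgd2 = t_wgd2,
    subst_rate = subst_rate,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_gene_families = as.integer(n_gene_families),
    n_single_copy = as.integer(n_single_copy),
    gene_length = as.integer(gene_length),
    repeat_length = as.integer(repeat_length),
    repeats_per_chrom = as.integer(repeats_per_chrom),
    repeat_contamination = repeat_contamination,
    ltr_per_chrom = as.integer(ltr_per_chrom),
    ltr_length = as.integer(ltr_length),
    ltr_internal_length = as.integer(ltr_internal_length),
    windows = windows, exchanges = exchanges, copy_loss = copy_loss,
    seed = as.integer(seed)), class = "scenario_spec")
  validate_scenario(spec)
  spec
}

#' Default planted homoeologous exchanges
#'
#' Three exchanges inside the octoploid nucleus, each spanning 15% of a
#' chromosome -- the proportion a multi-megabase exchange occupies on a
#' chromosome-scale assembly -- which exceeds the default minimum
#' exchange length (5 analysis windows of 12.5 kb at the default
#' chromosome size) without dominating the host chromosome's k-mer
#' profile.
#'
#' @param chrom_length chromosome length in bp.
#' @return data.frame with columns donor, recipient, chrom, start, end,
#'   time.
#' @export
default_exchanges <- function(chrom_length = 5e5) {
  L <- chrom_length
  data.frame(
    donor = c("B", "A", "C"),
    recipient = c("C", "B", "A"),
    chrom = c(1L, 2L, 3L),
    start = round(c(0.30, 0.10, 0.55) * L),
    end = round(c(0.45, 0.25, 0.70) * L),
    time = c(0.20, 0.30, 0.10),
    stringsAsFactors = FALSE)
}

validate_scenario <- function(spec) {
  s <- spec
  chk <- function(cond, event, why) {
    if (!cond) stop("invalid scenario: ", event, ": ", why, call. = FALSE)
  }
  chk(s$gene_length %% 3L == 0L, "gene_length", "must be a multiple of 3")
  chk(s$subst_rate >= 0, "subst_rate", "must be non-negative")
  chk(s$t_root >= s$t_do && s$t_root >= s$t_abc && s$t_abc >= s$t_ab,
      "lineage tree", "node ages must decrease from the root")
  if (s$model == "reticulate") {
    chk(s$t_hyb_ac < s$t_abc, "AC hybridization",
        "must be younger than the A-C divergence")
    chk(s$t_hyb_bd < s$t_root, "BD hybridization",
        "must be younger than the B-D divergence")
    chk(s$t_tet_oct <= s$t_hyb_ac, "tetraploid-octoploid split",
        "must be younger than the AC hybridization")
    chk(s$t_oct < s$t_hyb_ac && s$t_oct < s$t_hyb_bd, "octoploidization",
        "must be younger than both tetraploidizations")
    for (sub in names(s$windows)) {
      w <- s$windows[[sub]]
      chk(w[1] < w[2], paste0(sub, " insertion window"), "lower >= upper")
      chk(w[1] >= s$t_oct, paste0(sub, " insertion window"),
          "extends past the octoploid hybridization")
    }
  }
  if (!is.null(s$exchanges)) {
    e <- s$exchanges
    need <- c("donor", "recipient", "chrom", "start", "end", "time")
    chk(all(need %in% names(e)), "exchanges",
        paste("columns required:", paste(need, collapse = ", ")))
    for (i in seq_len(nrow(e))) {
      ev <- paste0("exchange ", i, " (", e$donor[i], "->", e$recipient[i], ")")
      chk(e$donor[i] != e$recipient[i], ev, "donor equals recipient")
      chk(e$start[i] >= 0 && e$end[i] <= s$chrom_length &&
            e$start[i] < e$end[i], ev, "interval outside chromosome bounds")
      chk(e$chrom[i] >= 1 && e$chrom[i] <= s$n_chromosomes, ev,
          "chromosome index out of range")
      if (s$model == "reticulate")
        chk(e$time[i] < s$t_oct, ev,
            "older than the hybridization creating its host nucleus")
    }
  }
  invisible(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Polyploidization scenario (", x$model, " model)\n", sep = "")
  cat("  chromosomes: ", x$n_chromosomes, " x ", x$chrom_length,
      " bp per subgenome\n", sep = "")
  cat("  gene families (1:2:4): ", x$n_gene_families,
      "; single-copy: ", x$n_single_copy, "\n", sep = "")
  cat("  exchanges planted: ",
      if (is.null(x$exchanges)) 0L else nrow(x$exchanges),
      "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# --- guide tree over genome copies -----------------------------------------

# Leaves are genome copies: out, tet_A, tet_C, oct_A .. oct_D.
# A node is list(age=, children=list(...)); a leaf is list(age=0, label=).
guide_tree <- function(spec) {
  leaf <- function(lab) list(age = 0, label = lab)
  node <- function(age, ...) list(age = age, children = list(...))
  if (spec$model == "reticulate") {
    node(spec$t_root,
         node(spec$t_abc,
              node(spec$t_ab,
                   node(spec$t_tet_oct, leaf("tet_A"), leaf("oct_A")),
                   leaf("oct_B")),
              node(spec$t_tet_oct, leaf("tet_C"), leaf("oct_C"))),
         node(spec$t_do, leaf("oct_D"), leaf("out")))
  } else {
    node(spec$t_root,
         leaf("out"),
         node(spec$t_wgd1,
              node(spec$t_speciation, leaf("tet_A"),
                   node(spec$t_wgd2, leaf("oct_A"), leaf("oct_B"))),
              node(spec$t_speciation, leaf("tet_C"),
                   node(spec$t_wgd2, leaf("oct_C"), leaf("oct_D")))))
  }
}

guide_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, guide_leaves))
}

# True pairwise divergence times (MRCA ages) between genome copies.
divergence_times <- function(tree) {
  leaves <- guide_leaves(tree)
  M <- matrix(0, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  fill <- function(node) {
    if (!is.null(node$label)) return(node$label)
    kids <- lapply(node$children, fill)
    for (i in seq_along(kids)) for (j in seq_along(kids)) {
      if (i < j) M[kids[[i]], kids[[j]]] <<- M[kids[[j]], kids[[i]]] <<-
          node$age
    }
    unlist(kids)
  }
  fill(tree)
  M
}

# Evolve a sequence down the guide tree; returns leaf sequences plus, for
# each leaf, its parent-node sequence and age (needed to branch exchanged
# copies at the exchange time).
evolve_guide <- function(root_seq, tree, rate) {
  leaves <- list()
  parents <- list()
  rec <- function(node, seq) {
    if (!is.null(node$label)) stop("guide root cannot be a leaf")
    for (ch in node$children) {
      if (!is.null(ch$label)) {
        parents[[ch$label]] <<- list(seq = seq, age = node$age)
        leaves[[ch$label]] <<- evolve_jc(seq, rate * node$age)
      } else {
        rec(ch, evolve_jc(seq, rate * (node$age - ch$age)))
      }
    }
  }
  rec(tree, root_seq)
  list(leaves = leaves, parents = parents)
}

# Genome-copy leaf -> (species, subgenome) bookkeeping.
leaf_meta <- function() {
  data.frame(
    leaf = c("out", "tet_A", "tet_C", "oct_A", "oct_B", "oct_C", "oct_D"),
    species = c("out", "tet", "tet", "oct", "oct", "oct", "oct"),
    subgenome = c("O", "A", "C", "A", "B", "C", "D"),
    stringsAsFactors = FALSE)
}

#' Canonical role labels for the 1:2:4 anchor unit
#'
#' Maps genome copies to the roles used by the topology census: `O`
#' (outgroup), `T1`/`T2` (tetraploid subgenomes) and `P1`..`P4`
#' (octoploid subgenomes).
#' @return named character vector, names are genome-copy labels.
#' @export
default_roles <- function() {
  c(out = "O", tet_A = "T1", tet_C = "T2",
    oct_A = "P1", oct_B = "P2", oct_C = "P3", oct_D = "P4")
}
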