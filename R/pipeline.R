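#' Default configuration for an end-to-end synthetic run
#'
#' @param outdir output directory.
#' @param seed master seed (drives the simulation).
#' @return named list accepted by [run_pipeline()].
#' @export
default_run_config <- function(outdir = tempfile("allorigin_run_"),
                               seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    scenario = list(model = "reticulate", n_gene_families = 60L,
                    n_single_copy = 10L, chrom_length = 200000L,
                    repeats_per_chrom = 40L, ltr_per_chrom = 15L,
                    exchanges = default_exchanges(200000L)),
    stages = c("simulate", "synteny", "trees", "census", "phase", "date"),
    k = 15L, min_count = 10L, min_fold = 2, window_size = 5000L,
    alpha = 0.05, min_exchange_windows = 5L, max_bridge_windows = 1L,
    n_subgenomes = 4L, bootstrap_n = 0L,
    mu = NULL, # subs/site/year; defaults to the scenario's rate
    t_calibration = 7.7)
}

plog <- function(con, level, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ",
                 paste0(..., collapse = ""))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full inference pipeline on a synthetic scenario
#'
#' Orchestrates simulate -> synteny -> trees -> census -> phase -> date,
#' writing per-stage TSV/Newick outputs, a Markdown report and a JSON
#' manifest (parameters, seed and md5 checksums of all outputs) under
#' `config$outdir`. Reruns with an identical configuration reproduce
#' byte-identical outputs and manifests.
#'
#' @param config list as produced by [default_run_config()] (possibly
#'   modified), or a path to a YAML file with the same fields.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  cfg <- base
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$outdir, "run.log"), "w")
  on.exit(close(logf))
  plog(logf, "INFO", "run start; seed=", cfg$seed,
       "; k=", cfg$k, "; window_size=", cfg$window_size,
       "; alpha=", cfg$alpha,
       "; min_exchange_windows=", cfg$min_exchange_windows,
       "; min_count=", cfg$min_count, "; min_fold=", cfg$min_fold)
  res <- list(config = cfg)
  outputs <- character(0)
  tsv <- function(x, name) {
    f <- file.path(cfg$outdir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
    f
  }
  stage <- function(name) name %in% cfg$stages

  # simulate ---------------------------------------------------------------
  sc_args <- cfg$scenario
  sc_args$seed <- cfg$seed
  spec <- do.call(scenario_spec, sc_args)
  if (is.null(cfg$mu)) cfg$mu <- spec$subst_rate * 1e-6
  sim <- simulate_scenario(spec)
  if (stage("simulate")) {
    plog(logf, "INFO", "simulate: ", nrow(sim$chrom_table), " chromosomes, ",
         nrow(sim$genes), " gene copies")
    simdir <- file.path(cfg$outdir, "simulate")
    outputs <- c(outputs, write_simulation(sim, simdir))
    write_scenario_config(spec, file.path(simdir, "scenario.yaml"))
    outputs <- c(outputs, file.path(simdir, "scenario.yaml"))
  }
  res$sim <- sim

  # synteny ----------------------------------------------------------------
  if (stage("synteny")) {
    syn <- synteny_anchor_groups(sim$genes)
    plog(logf, "INFO", "synteny: ", length(syn$orthogroups$groups),
         " orthogroups, ", nrow(syn$anchors$groups), " anchor groups")
    tsv(syn$blocks, "synteny_blocks.tsv")
    tsv(syn$anchors$members, "anchor_members.tsv")
    res$synteny <- syn
  }

  # trees + census ----------------------------------------------------------
  if (stage("trees") || stage("census")) {
    trees <- anchor_gene_trees(sim)
    plog(logf, "INFO", "trees: ", length(trees), " anchor gene trees")
    if (stage("trees")) {
      tf <- file.path(cfg$outdir, "gene_trees.nwk")
      ape::write.tree(do.call(c, unname(trees)), tf)
      outputs <- c(outputs, tf)
    }
    res$trees <- trees
    if (stage("census")) {
      cen <- census(trees, sim$roles)
      plog(logf, "INFO", "census verdict: ", cen$verdict,
           " (plurality fraction ", round(cen$classes$fraction[1], 3), ")")
      tsv(cen$classes, "topology_census.tsv")
      res$census <- cen
    }
  }

  # phase ------------------------------------------------------------------
  if (stage("phase")) {
    part <- phase_subgenomes(
      sim$genomes$oct, n_subgenomes = cfg$n_subgenomes, k = cfg$k,
      min_count = cfg$min_count, min_fold = cfg$min_fold,
      window_size = cfg$window_size, alpha = cfg$alpha,
      min_exchange_windows = cfg$min_exchange_windows,
      max_bridge_windows = cfg$max_bridge_windows, seed = cfg$seed)
    plog(logf, "INFO", "phase: ", length(unique(part$assignment)),
         " subgenomes, ", nrow(part$exchanges), " exchange segments")
    tsv(data.frame(chrom = names(part$assignment),
                   subgenome = unname(part$assignment)),
        "subgenome_assignment.tsv")
    tsv(part$windows, "window_enrichment.tsv")
    tsv(part$exchanges, "exchange_segments.tsv")
    res$partition <- part
  }

  # date -------------------------------------------------------------------
  if (stage("date")) {
    lt <- sim$ltrs[sim$ltrs$chrom %in%
                     names(as_seq_vector(sim$genomes$oct)), ]
    lt <- ltr_insertion_ages(sim$genomes$oct, lt, spec$ltr_length, cfg$mu)
    excl <- rep(FALSE, nrow(lt))
    if (!is.null(res$partition) && nrow(res$partition$exchanges)) {
      ex <- res$partition$exchanges
      mid <- (lt$start + lt$end) / 2
      for (i in seq_len(nrow(ex)))
        excl <- excl | (lt$chrom == ex$chrom[i] & mid >= ex$start[i] &
                          mid < ex$end[i])
    }
    ci <- divergence_hybridization_window(lt, exclude = excl,
                                          min_elements = 10L)
    tsv(ci, "ltr_insertion_windows.tsv")
    pairs <- rbind(
      c("calibration", "tet_A", "out"),
      c("A-B", "tet_A", "oct_B"),
      c("A-C", "tet_A", "tet_C"),
      c("A-D", "tet_A", "oct_D"),
      c("tet-oct", "tet_A", "oct_A"))
    ksmed <- apply(pairs, 1L, function(r) {
      stats::median(ks_between_copies(sim, r[2], r[3]), na.rm = TRUE)
    })
    dating <- data.frame(pair = pairs[, 1], leaf1 = pairs[, 2],
                         leaf2 = pairs[, 3], median_ks = ksmed,
                         t_est = ks_ratio_dating(ksmed, ksmed[1],
                                                 cfg$t_calibration),
                         t_true = mapply(function(a, b) sim$divergence[a, b],
                                         pairs[, 2], pairs[, 3]))
    tsv(dating, "ks_dating.tsv")
    plog(logf, "INFO", "date: LTR windows for ",
         nrow(ci), " subgenomes; Ks dating for ", nrow(dating), " pairs")
    res$ltr_windows <- ci
    res$dating <- dating
  }

  # report + manifest --------------------------------------------------------
  rep_file <- file.path(cfg$outdir, "report.md")
  lines <- c("# Polyploid origin inference report", "",
             paste0("Scenario model: ", spec$model, "; seed: ", cfg$seed), "")
  if (!is.null(res$census)) {
    lines <- c(lines, "## Topology census", "",
               paste0("Favored model: ", res$census$verdict,
                      " (plurality fraction ",
                      sprintf("%.3f", res$census$classes$fraction[1]), ")"),
               "", utils::capture.output(print(res$census)), "")
  }
  if (!is.null(res$partition)) {
    lines <- c(lines, "## Subgenome phasing", "",
               paste0(names(res$partition$assignment), ": ",
                      unname(res$partition$assignment)), "",
               paste0("Exchange segments called: ",
                      nrow(res$partition$exchanges)), "")
  }
  if (!is.null(res$ltr_windows)) {
    lines <- c(lines, "## LTR insertion-time windows (MY)", "",
               utils::capture.output(print(res$ltr_windows,
                                           row.names = FALSE)), "")
  }
  if (!is.null(res$dating)) {
    lines <- c(lines, "## Ks-ratio dating (MY)", "",
               utils::capture.output(print(res$dating, row.names = FALSE)),
               "")
  }
  writeLines(lines, rep_file)
  outputs <- c(outputs, rep_file)
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "outdir")],
    seed = cfg$seed,
    files = as.list(tools::md5sum(sort(outputs))))
  names(manifest$files) <- basename(sort(outputs))
  mf <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  plog(logf, "INFO", "run complete; manifest: ", mf)
  invisible(c(res, list(manifest = mf)))
}
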