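#' Write a simulated complex to disk in standard formats
#'
#' Emits, under `dir`: one FASTA per species (80-column wrapped), one GFF3
#' per species (gene/mRNA/CDS features, 1-based inclusive, strand `+`),
#' and tab-separated truth tables (`chromosomes.tsv`, `genes.tsv`,
#' `ltrs.tsv`, `repeats.tsv`, `exchanges.tsv`, `divergence.tsv`) whose
#' headers match the columns documented in [simulate_scenario()].
#'
#' @param sim a `polyploid_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(sim$genomes)) {
    fa <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(sim$genomes[[sp]], fa, width = 80L)
    gff <- file.path(dir, paste0(sp, ".gff3"))
    write_gff3(sim$genes[sim$genes$genome == sp, ], gff)
    files <- c(files, fa, gff)
  }
  tsv <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(files,
             tsv(sim$chrom_table, "chromosomes.tsv"),
             tsv(sim$genes[, setdiff(names(sim$genes), "cds")], "genes.tsv"),
             tsv(sim$ltrs, "ltrs.tsv"),
             tsv(sim$repeats, "repeats.tsv"))
  if (!is.null(sim$exchanges))
    files <- c(files, tsv(sim$exchanges, "exchanges.tsv"))
  dv <- as.data.frame(sim$divergence)
  dv <- cbind(leaf = rownames(sim$divergence), dv)
  files <- c(files, tsv(dv, "divergence.tsv"))
  invisible(files)
}

# gene/mRNA/CDS hierarchy; internal coordinates are 0-based half-open,
# GFF3 is 1-based inclusive.
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) == 0) return(invisible(path))
  g <- genes[order(genes$chrom, genes$start), ]
  lines <- character(3L * nrow(g))
  for (i in seq_len(nrow(g))) {
    s1 <- g$start[i] + 1L
    e1 <- g$end[i]
    id <- g$gene[i]
    base <- paste(g$chrom[i], "allorigin", c("gene", "mRNA", "CDS"),
                  s1, e1, ".", "+", c(".", ".", "0"),
                  c(paste0("ID=", id),
                    paste0("ID=", id, ".t1;Parent=", id),
                    paste0("ID=", id, ".t1.cds;Parent=", id, ".t1")),
                  sep = "\t")
    lines[(3L * i - 2L):(3L * i)] <- base
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write reads as FASTQ (Phred+33, constant Q30)
#'
#' @param reads data.frame from [simulate_reads()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("?", nchar(reads$seq)) # '?' = Q30 in Phred+33
  out <- rbind(paste0("@", reads$id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame of reads
#' @param path FASTQ file.
#' @return data.frame with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file plus genome FASTA
#'
#' Extracts `gene` features and their CDS sequence from the genome,
#' returning the gene-model table used by the synteny stage (0-based
#' half-open coordinates, per-chromosome rank order).
#'
#' @param gff3 path to a GFF3 annotation.
#' @param fasta path to the matching genome FASTA.
#' @param genome label to store in the `genome` column.
#' @return data.frame with columns `gene`, `genome`, `chrom`, `start`,
#'   `end`, `rank`, `cds`.
#' @export
read_gene_models <- function(gff3, fasta, genome = "genome") {
  gr <- rtracklayer::import(gff3)
  gr <- gr[gr$type == "gene"]
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*", "", names(dna))
  df <- data.frame(
    gene = gr$ID, genome = genome,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  df$rank <- stats::ave(df$start, df$chrom, FUN = function(x) seq_along(x) - 1L)
  df$cds <- as.character(Biostrings::subseq(
    dna[df$chrom], start = df$start + 1L, end = df$end))
  rownames(df) <- NULL
  df
}

#' Read or write a scenario configuration file
#'
#' The configuration is a YAML rendering of the [scenario_spec()] fields;
#' `exchanges` and `copy_loss` are stored as lists of records.
#'
#' @param path YAML file.
#' @return for `read_scenario_config`, a `scenario_spec`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$exchanges))
    y$exchanges <- do.call(rbind, lapply(y$exchanges, as.data.frame))
  if (!is.null(y$copy_loss))
    y$copy_loss <- do.call(rbind, lapply(y$copy_loss, as.data.frame))
  if (!is.null(y$windows)) y$windows <- lapply(y$windows, unlist)
  do.call(scenario_spec, y)
}

#' @rdname read_scenario_config
#' @param spec a `scenario_spec` to serialize.
#' @export
write_scenario_config <- function(spec, path) {
  y <- unclass(spec)
  if (!is.null(y$exchanges))
    y$exchanges <- lapply(seq_len(nrow(y$exchanges)),
                          function(i) as.list(y$exchanges[i, ]))
  if (!is.null(y$copy_loss))
    y$copy_loss <- lapply(seq_len(nrow(y$copy_loss)),
                          function(i) as.list(y$copy_loss[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
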