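# Alignments are named character vectors of equal-length rows; gaps are
# "-". Codon alignments keep gaps in whole-codon units.

check_alignment <- function(aln) {
  if (length(aln) < 1) stop("empty alignment")
  if (length(unique(nchar(aln))) != 1)
    stop("alignment rows have unequal lengths")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment rows must have unique names")
  invisible(aln)
}

aln_matrix <- function(aln) {
  check_alignment(aln)
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

#' Progressive multiple alignment of protein sequences
#'
#' Aligns protein sequences with MAFFT (progressive FFT-NS-2, default
#' parameters), which must be available on the PATH. Input order is
#' preserved and no residues are deleted.
#'
#' @param seqs named character vector of protein sequences (>= 2).
#' @return named character vector of aligned rows (equal lengths).
#' @export
align_progressive <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZUO*]", toupper(seqs))
  if (any(bad))
    stop("illegal characters in sequence '", names(seqs)[which(bad)[1]], "'")
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", seqs), fin)
  status <- system2("mafft", c("--quiet", "--anysymbol", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  out <- Biostrings::readBStringSet(fout)
  aln <- stats::setNames(toupper(as.character(out)), names(out))
  aln[names(seqs)]
}

#' Remove alignment columns exceeding a gap fraction
#'
#' Keeps exactly the columns whose gap fraction is `<= max_gap_fraction`,
#' preserving column order. For codon alignments the rule is applied per
#' codon column (all three positions dropped together).
#'
#' @param aln alignment (named character vector).
#' @param max_gap_fraction maximum tolerated fraction of gaps per column.
#' @param codon treat the alignment as codons (column unit of 3).
#' @return the trimmed alignment.
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.2, codon = FALSE) {
  m <- aln_matrix(aln)
  if (codon) {
    if (ncol(m) %% 3L != 0L) stop("codon alignment length not divisible by 3")
    grp <- rep(seq_len(ncol(m) / 3L), each = 3L)
    gapfrac <- vapply(split(seq_len(ncol(m)), grp), function(j) {
      mean(colMeans(m[, j, drop = FALSE] == "-"))
    }, numeric(1))
    keep <- rep(gapfrac <= max_gap_fraction, each = 3L)
  } else {
    keep <- colMeans(m == "-") <= max_gap_fraction
  }
  if (!any(keep))
    stop("all columns removed; increase max_gap_fraction")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, names(aln))
}

#' Translate CDS to protein
#' @param cds character vector of CDS sequences (length divisible by 3).
#' @return character vector of protein sequences (stops as `*`).
#' @export
translate_cds <- function(cds) {
  out <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE))
  stats::setNames(out, names(cds))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column becomes the source codon; protein gaps become
#' `---`. Every CDS must translate exactly to its ungapped protein row.
#'
#' @param protein_aln aligned proteins (named character vector).
#' @param cds_map named character vector or list of CDS sequences, names
#'   matching the alignment rows.
#' @return codon alignment (named character vector).
#' @export
backtranslate <- function(protein_aln, cds_map) {
  check_alignment(protein_aln)
  out <- vapply(names(protein_aln), function(id) {
    row <- strsplit(protein_aln[[id]], "", fixed = TRUE)[[1]]
    cds <- cds_map[[id]]
    if (is.null(cds)) stop("no CDS provided for '", id, "'")
    prot <- strsplit(translate_cds(cds), "", fixed = TRUE)[[1]]
    res <- row[row != "-"]
    if (length(res) != length(prot) || any(res != prot)) {
      at <- if (length(res) != length(prot)) length(prot)
            else which(res != prot)[1]
      stop("CDS for '", id, "' does not translate to its aligned protein",
           " (residue ", at, ")")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    filled <- character(length(row))
    filled[row == "-"] <- "---"
    filled[row != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  stats::setNames(out, names(protein_aln))
}

#' Concatenate alignments sharing a taxon set
#'
#' @param alns list of alignments with identical row names.
#' @return concatenated alignment with a `partitions` attribute
#'   (data.frame of part name, start, end columns, 1-based).
#' @export
concat_alignment <- function(alns) {
  if (length(alns) == 0) stop("no alignments supplied")
  taxa <- names(alns[[1]])
  for (i in seq_along(alns)) {
    check_alignment(alns[[i]])
    miss <- setdiff(taxa, names(alns[[i]]))
    extra <- setdiff(names(alns[[i]]), taxa)
    if (length(miss) || length(extra))
      stop("taxon mismatch in part ", i, ": missing ",
           paste(miss, collapse = ","), ifelse(length(extra), paste0(
             "; unexpected ", paste(extra, collapse = ",")), ""))
  }
  widths <- vapply(alns, function(a) nchar(a[[1]]), numeric(1))
  ends <- cumsum(widths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- vapply(taxa, function(tx) {
    paste(vapply(alns, function(a) a[[tx]], character(1)), collapse = "")
  }, character(1))
  out <- stats::setNames(out, taxa)
  attr(out, "partitions") <- data.frame(
    part = if (is.null(names(alns))) paste0("part", seq_along(alns))
           else names(alns),
    start = starts, end = ends)
  out
}
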