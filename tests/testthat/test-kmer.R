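rand_dna <- function(n, seed) {
  allorigin:::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

test_that("k-mer window count arithmetic and canonical strands", {
  seq16 <- c(chr1 = "ACGTACGTACGTACGT")
  km <- count_kmers(seq16, k = 11)
  expect_equal(unname(km$valid["chr1"]), 6)     # 16 - 11 + 1
  expect_equal(sum(km$counts), 6L)
  # a sequence and its reverse complement count identically
  s <- c(chr1 = rand_dna(500, 1))
  rc <- c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s[[1]]))))
  k1 <- count_kmers(s, 15)
  k2 <- count_kmers(rc, 15)
  expect_identical(k1$kmers, k2$kmers)
  expect_identical(unname(k1$counts), unname(k2$counts))
  expect_error(count_kmers(s, 14), "odd")
  expect_error(count_kmers(s, 9), "between")
  # ambiguous bases break k-mers: 25 bp with N at position 13 leaves
  # two valid 11-mer windows on each side
  kn <- count_kmers(c(chr1 = paste0(strrep("ACGT", 3), "N",
                                    strrep("ACGT", 3))), 11)
  expect_equal(unname(kn$valid["chr1"]), 4)
})

test_that("counts equal a naive dictionary recount", {
  s <- rand_dna(10000, 7)
  km <- count_kmers(c(chr = s), k = 15)
  oracle <- naive_kmer_count(s, 15)
  expect_equal(ncol(km$counts), length(oracle))
  expect_identical(colnames(km$counts), names(oracle))
  expect_equal(unname(km$counts[1, ]), unname(oracle))
})

test_that("differential k-mer selection keeps group-specific k-mers", {
  km <- structure(list(
    kmers = c("k1", "k2", "k3"),
    counts = matrix(c(100L, 90L, 0L, 0L,   # k1: group g1 only
                      25L, 25L, 25L, 25L,  # k2: uniform
                      0L, 0L, 80L, 70L),   # k3: group g2 only
                    nrow = 4,
                    dimnames = list(paste0("c", 1:4), c("k1", "k2", "k3"))),
    lengths = rep(1e5, 4), valid = stats::setNames(rep(1e5, 4),
                                                   paste0("c", 1:4)),
    k = 15L), class = "kmer_matrix")
  groups <- c(c1 = "g1", c2 = "g1", c3 = "g2", c4 = "g2")
  sets <- select_differential_kmers(km, groups, min_fold = 2, min_count = 10)
  expect_equal(sets$g1, "k1")
  expect_equal(sets$g2, "k3")
})

test_that("chromosome clustering separates planted k-mer sets", {
  sim <- simulate_scenario(small_spec(seed = 5, exchanges = NULL))
  km <- count_kmers(sim$genomes$oct, 15, min_total = 10)
  cl <- cluster_chromosomes(km, n_subgenomes = 4, seed = 2)
  truth <- stats::setNames(sim$chrom_table$subgenome, sim$chrom_table$chrom)
  expect_equal(length(unique(cl)), 4L)
  # perfect partition: each cluster maps to exactly one true subgenome
  tab <- table(cl, truth[names(cl)])
  expect_true(all(rowSums(tab > 0) == 1))
  # column (k-mer) permutation leaves the partition unchanged
  km2 <- km
  perm <- rev(seq_len(ncol(km$counts)))
  km2$counts <- km$counts[, perm]
  km2$kmers <- km$kmers[perm]
  expect_identical(cluster_chromosomes(km2, 4, seed = 2), cl)
  expect_error(cluster_chromosomes(km, n_subgenomes = 99), "more subgenomes")
})

test_that("window enrichment p-values equal exact tail enumeration", {
  sim <- simulate_scenario(small_spec(seed = 5, exchanges = NULL))
  part <- phase_subgenomes(sim$genomes$oct, seed = 2)
  w <- part$windows
  labs <- names(part$sets)
  M <- colSums(as.matrix(w[, labs]))
  N <- sum(M)
  picked <- which(!is.na(w$label))[1:5]
  for (i in picked) {
    s <- w$label[i]
    q <- w[i, s]
    kdraw <- w$total[i]
    # independent exact hypergeometric upper tail via choose()
    js <- q:min(M[s], kdraw)
    p_oracle <- sum(exp(lchoose(M[s], js) + lchoose(N - M[s], kdraw - js) -
                          lchoose(N, kdraw)))
    expect_equal(w$p[i], p_oracle, tolerance = 1e-10)
  }
  # a window with no specific k-mers is unlabeled
  expect_true(all(is.na(w$label[w$total == 0])))
  # single-set windows get that label with tiny q
  pure <- w[!is.na(w$label) & w$total > 100, ]
  hit_mat <- as.matrix(pure[, labs])
  only_one <- rowSums(hit_mat > 0) == 1
  expect_true(all(pure$label[only_one] ==
                    labs[apply(hit_mat[only_one, , drop = FALSE], 1,
                               which.max)]))
  expect_error(window_enrichment(sim$genomes$oct, part$sets,
                                 window_size = 10), "at least k")
})

test_that("exchange calling applies run, bridge and length rules", {
  mk_enr <- function(labels) {
    n <- length(labels)
    data.frame(chrom = "c1", window = seq_len(n) - 1L,
               start = (seq_len(n) - 1L) * 100L, end = seq_len(n) * 100L,
               total = 10L, label = labels, stringsAsFactors = FALSE)
  }
  hostA <- c(c1 = "A")
  # single discordant window at min length 5: no call
  e1 <- mk_enr(c("A", "A", "B", "A", "A", "A", "A", "A", "A", "A"))
  expect_equal(nrow(call_exchanges(e1, hostA, 5, 1)), 0L)
  # 6-window discordant run with one interior unlabeled window: one call
  e2 <- mk_enr(c("A", "B", "B", "B", NA, "B", "B", "B", "A", "A"))
  x2 <- call_exchanges(e2, hostA, 5, 1)
  expect_equal(nrow(x2), 1L)
  expect_equal(x2$donor, "B")
  expect_equal(c(x2$start, x2$end), c(100L, 800L))
  # two runs separated by more than max_bridge unlabeled windows
  e3 <- mk_enr(c("B", "B", "B", "B", "B", NA, NA, "B", "B", "B", "B", "B"))
  x3 <- call_exchanges(e3, hostA, 5, 1)
  expect_equal(nrow(x3), 2L)
  # a host-labeled interior window always breaks the run
  e4 <- mk_enr(c("B", "B", "B", "A", "B", "B", "B", "A", "A", "A"))
  expect_equal(nrow(call_exchanges(e4, hostA, 5, 1)), 0L)
})

test_that("interval assignment follows the midpoint rule", {
  part <- structure(list(
    assignment = c(c1 = "A"), lengths = c(c1 = 1000L),
    exchanges = data.frame(chrom = "c1", start = 200L, end = 400L,
                           host = "A", donor = "B",
                           stringsAsFactors = FALSE)),
    class = "subgenome_partition")
  expect_equal(assign_interval(part, "c1", 250, 350), "B")
  expect_equal(assign_interval(part, "c1", 500, 600), "A")
  # straddling: midpoint at 390 is inside the exchange
  expect_equal(assign_interval(part, "c1", 380, 400), "B")
  # straddling: midpoint at 405 is outside
  expect_equal(assign_interval(part, "c1", 390, 420), "A")
  expect_error(assign_interval(part, "c1", 900, 1100), "outside")
  expect_error(assign_interval(part, "c9", 1, 2), "unknown")
})

test_that("read classification follows specific k-mer content", {
  sim <- simulate_scenario(small_spec(seed = 6, exchanges = NULL))
  part <- phase_subgenomes(sim$genomes$oct, seed = 2)
  truth <- stats::setNames(sim$chrom_table$subgenome, sim$chrom_table$chrom)
  cl2truth <- vapply(split(truth[names(part$assignment)], part$assignment),
                     function(x) names(sort(table(x), decreasing = TRUE))[1],
                     character(1))
  # reads from subgenome A chromosomes only
  achr <- sim$chrom_table$chrom[sim$chrom_table$subgenome == "A" &
                                  sim$chrom_table$species == "oct"]
  reads <- simulate_reads(sim$genomes$oct[achr], read_length = 100,
                          coverage = 3, seed = 9)
  rc <- read_composition(reads, sim$genomes$oct, part)
  assigned <- rc$reads$label[!is.na(rc$reads$label)]
  expect_gt(length(assigned), 50)
  expect_gte(mean(cl2truth[assigned] == "A"), 0.95)
  # a read without any specific k-mer stays unassigned, as does a read
  # shorter than k
  rc2 <- read_composition(c(strrep("A", 100), "ACGT"), sim$genomes$oct,
                          part)
  expect_true(all(is.na(rc2$reads$label)))
})
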