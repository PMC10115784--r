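test_that("scenario validation rejects inconsistent event ordering", {
  expect_error(small_spec(t_hyb_ac = 6), "AC hybridization")
  expect_error(small_spec(t_oct = 1.5), "octoploidization")
  expect_error(small_spec(exchanges = data.frame(
    donor = "B", recipient = "B", chrom = 1, start = 0, end = 1e4,
    time = 0.1)), "donor equals recipient")
  expect_error(small_spec(exchanges = data.frame(
    donor = "B", recipient = "C", chrom = 1, start = 0, end = 2e5,
    time = 0.1)), "bounds")
  expect_error(small_spec(exchanges = data.frame(
    donor = "B", recipient = "C", chrom = 1, start = 0, end = 1e4,
    time = 0.6)), "host nucleus")
  expect_error(small_spec(gene_length = 100), "multiple of 3")
})

test_that("identical spec and seed give byte-identical output", {
  s1 <- simulate_scenario(small_spec(seed = 11))
  s2 <- simulate_scenario(small_spec(seed = 11))
  expect_identical(as.character(s1$genomes$oct), as.character(s2$genomes$oct))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$ltrs, s2$ltrs)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  s3 <- simulate_scenario(small_spec(seed = 12))
  expect_false(identical(as.character(s1$genomes$oct),
                         as.character(s3$genomes$oct)))
})

test_that("zero substitution rate yields identical homologous copies", {
  sim <- simulate_scenario(small_spec(subst_rate = 0, exchanges = NULL))
  g <- sim$genes[!sim$genes$single_copy, ]
  for (f in unique(g$family))
    expect_length(unique(g$cds[g$family == f]), 1L)
})

test_that("pairwise gene divergence matches the JC expectation", {
  # all progenitors split at 5 MY (star radiation); expected p-distance
  # between any two subgenome copies is 3/4 (1 - exp(-4/3 * 2 t r))
  rate <- 0.005
  sim <- simulate_scenario(small_spec(
    t_ab = 5, t_abc = 5, t_do = 5, t_root = 5, subst_rate = rate,
    n_gene_families = 40L, n_single_copy = 0L, exchanges = NULL, seed = 3))
  g <- sim$genes
  leaves <- c("oct_A", "oct_B", "oct_C", "oct_D")
  ps <- c()
  nsites <- 0
  for (f in unique(g$family)) {
    cds <- stats::setNames(g$cds[g$family == f], g$leaf[g$family == f])
    m <- do.call(rbind, strsplit(cds[leaves], ""))
    for (i in 1:3) for (j in (i + 1):4) {
      ps <- c(ps, mean(m[i, ] != m[j, ]))
      nsites <- nsites + ncol(m)
    }
  }
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 2 * 5 * rate))
  se <- sqrt(p_exp * (1 - p_exp) / nsites)
  # pairs share tree paths, so allow 3 SE on the pooled mean with an
  # effective-sample deflation for non-independence
  expect_lt(abs(mean(ps) - p_exp), 3 * se * sqrt(6))
})

test_that("gene families are planted at an exact 1:2:4 copy ratio", {
  sim <- simulate_scenario(small_spec(seed = 4))
  g <- sim$genes[!sim$genes$single_copy, ]
  tab <- table(g$family, g$genome)
  expect_true(all(tab[, "out"] == 1))
  expect_true(all(tab[, "tet"] == 2))
  expect_true(all(tab[, "oct"] == 4))
  gs <- sim$genes[sim$genes$single_copy, ]
  tabs <- table(gs$family, gs$genome)
  expect_true(all(tabs == 1))
})

test_that("copy loss removes exactly the named copies", {
  sim <- simulate_scenario(small_spec(
    copy_loss = data.frame(family = 1L, leaf = "oct_B"), seed = 5))
  g1 <- sim$genes[sim$genes$family == 1L, ]
  expect_false("oct_B" %in% g1$leaf)
  expect_equal(nrow(g1), 6L)
})

test_that("repeat and LTR insertion ages stay inside their windows", {
  sim <- simulate_scenario(small_spec(seed = 6))
  w <- sim$spec$windows
  for (s in c("A", "B", "C", "D")) {
    rep_s <- sim$repeats[sim$repeats$motif == s & sim$repeats$host == s, ]
    expect_true(all(rep_s$age >= w[[s]][1] & rep_s$age <= w[[s]][2]))
    ltr_s <- sim$ltrs[sim$ltrs$origin == s, ]
    expect_true(all(ltr_s$age >= w[[s]][1] & ltr_s$age <= w[[s]][2]))
  }
})

test_that("exchanged intervals carry donor-derived sequence", {
  sim <- simulate_scenario(small_spec(seed = 7))
  rate <- sim$spec$subst_rate
  seqs <- as.character(sim$genomes$oct)
  ex <- sim$exchanges[1, ]
  donor_chrom <- sub("oct_[A-D]", paste0("oct_", ex$donor), ex$chrom)
  reg <- function(s) strsplit(substr(s, ex$start + 1, ex$end), "")[[1]]
  rec <- reg(seqs[[ex$chrom]])
  don <- reg(seqs[[donor_chrom]])
  p_obs <- mean(rec != don)
  # both copies descend from the donor lineage at the exchange time
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 2 * ex$time * rate))
  expect_lt(abs(p_obs - p_exp), 5 * sqrt(p_exp * (1 - p_exp) / length(rec)))
  # and the recipient segment is far closer to the donor than to the
  # unexchanged copy of its own (host) lineage in the tetraploid
  tet_host <- as.character(sim$genomes$tet)[[
    sub("^oct", "tet", sub("oct_[A-D]", paste0("oct_", ex$recipient),
                           ex$chrom))]]
  expect_gt(mean(rec != reg(tet_host)), 4 * p_obs)
})

test_that("simulated reads match coverage, determinism and source labels", {
  sim <- simulate_scenario(small_spec(seed = 8, exchanges = NULL))
  rd <- simulate_reads(sim, species = "oct", read_length = 100,
                       coverage = 2, seed = 21)
  lambda <- 2 * 12 * 1e5 / 100
  expect_lt(abs(nrow(rd) - lambda), 5 * sqrt(lambda))
  rd2 <- simulate_reads(sim, species = "oct", read_length = 100,
                        coverage = 2, seed = 21)
  expect_identical(rd, rd2)
  # labels proportional to subgenome lengths (equal here): multinomial
  tab <- table(rd$subgenome)
  expect_true(all(abs(tab / nrow(rd) - 0.25) <
                    3 * sqrt(0.25 * 0.75 / nrow(rd))))
  expect_error(simulate_reads(sim, species = "oct", read_length = 2e5,
                              coverage = 1), "read_length")
  expect_error(simulate_reads(sim, species = "oct", read_length = 100,
                              coverage = 0), "coverage")
})
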