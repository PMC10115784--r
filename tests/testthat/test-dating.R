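test_that("LTR insertion age follows T = K / (2 mu)", {
  same <- strrep("ACGT", 75)
  r0 <- ltr_insertion_age(same, same, mu = 1e-8)
  expect_equal(r0$p, 0)
  expect_equal(r0$T, 0)
  # 300 bp with 6 mismatches: p = 0.02
  mut <- same
  substr(mut, 1, 6) <- "GTACGT"  # flips 6 positions
  mism <- sum(strsplit(same, "")[[1]] != strsplit(mut, "")[[1]])
  r <- ltr_insertion_age(same, mut, mu = 1e-8)
  expect_equal(r$p, mism / 300)
  expect_equal(r$K, -0.75 * log(1 - 4 * r$p / 3))
  expect_equal(r$T, r$K / (2 * 1e-8) / 1e6)
  expect_warning(rs <- ltr_insertion_age(strrep("A", 100), strrep("C", 100),
                                         mu = 1e-8), "saturated")
  expect_true(is.na(rs$T))
  expect_error(ltr_insertion_age(same, same), "mu")
})

test_that("simulated elements are dated within binomial noise", {
  sim <- simulate_scenario(small_spec(seed = 9, exchanges = NULL))
  mu <- sim$spec$subst_rate * 1e-6
  lt <- sim$ltrs[grepl("^oct", sim$ltrs$chrom), ]
  lt <- ltr_insertion_ages(sim$genomes$oct, lt, sim$spec$ltr_length, mu)
  # per-element ages are noisy; the mean error across elements must be
  # near zero (no bias)
  expect_lt(abs(mean(lt$age_est - lt$age)), 0.35)
  expect_gt(stats::cor(lt$age_est, lt$age), 0.7)
})

test_that("percentile windows follow the quantile definition", {
  ages <- list(A = seq(1, 4, length.out = 40))
  ci <- divergence_hybridization_window(ages, min_elements = 20)
  expect_equal(ci$lower, 1 + 0.975 * 3 / 39, tolerance = 1e-10)
  expect_equal(ci$upper, 4 - 0.975 * 3 / 39, tolerance = 1e-10)
  cc <- divergence_hybridization_window(list(B = rep(2.5, 30)))
  expect_equal(c(cc$lower, cc$upper), c(2.5, 2.5))
  expect_error(divergence_hybridization_window(list(D = 1:3)), "subgenome D")
})

test_that("NG86 worked example and symmetry", {
  # GGGGGA vs GGGGGG: one change at a 4-fold site
  r <- ng86_ka_ks("GGGGGA", "GGGGGG")
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.5)
  expect_equal(r$Ks, -0.75 * log(1 / 3))
  expect_equal(r$Ka, 0)
  r2 <- ng86_ka_ks("GGGGGG", "GGGGGA")
  expect_equal(r2$Ks, r$Ks)
  expect_equal(r2$Ka, r$Ka)
  same <- ng86_ka_ks("ATGGCT", "ATGGCT")
  expect_equal(c(same$Ks, same$Ka), c(0, 0))
  expect_error(ng86_ka_ks("ATGTAAGCT", "ATGTAAGCT"), "codon index 2")
})

test_that("NG86 agrees with exhaustive path enumeration on codon pairs", {
  codons <- c("GGG", "GGA", "ATG", "ATA", "CTT", "CGA", "AAA", "AGG",
              "TTT", "TAC", "TGT", "CAA")
  for (c1 in codons) for (c2 in codons) {
    # saturated toy pairs warn by design; the values are still compared
    got <- suppressWarnings(ng86_ka_ks(paste0("ATG", c1),
                                       paste0("ATG", c2)))
    want <- oracle_ng86(paste0("ATG", c1), paste0("ATG", c2))
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
  }
})

test_that("Ks-ratio dating is linear and anchored at the calibration", {
  expect_equal(ks_ratio_dating(0.25, 0.25), 7.7)
  expect_equal(ks_ratio_dating(0, 0.25), 0)
  expect_equal(ks_ratio_dating(0.5, 0.25), 15.4)
  expect_equal(ks_ratio_dating(0.1, 0.2, t_calibration = 10), 5)
  # homogeneity of degree 1 in the query
  expect_equal(ks_ratio_dating(3 * 0.04, 0.2), 3 * ks_ratio_dating(0.04, 0.2))
  expect_error(ks_ratio_dating(0.1, 0), "positive")
})

test_that("Ks histogram peaks recover planted modes", {
  set.seed(5)
  uni <- pmax(stats::rnorm(500, 0.5, 0.05), 0)
  p1 <- ks_distribution_peaks(uni, bin_width = 0.05)
  expect_true(p1$has_peak)
  expect_equal(nrow(p1$peaks), 1L)
  expect_lt(abs(p1$peaks$ks - 0.5), 0.05)
  bim <- c(pmax(stats::rnorm(400, 0.2, 0.03), 0),
           pmax(stats::rnorm(400, 0.8, 0.05), 0))
  p2 <- ks_distribution_peaks(bim, bin_width = 0.05)
  expect_equal(nrow(p2$peaks), 2L)
  expect_lt(abs(p2$peaks$ks[1] - 0.2), 0.06)
  expect_lt(abs(p2$peaks$ks[2] - 0.8), 0.06)
  p0 <- ks_distribution_peaks(numeric(0))
  expect_false(p0$has_peak)
})
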