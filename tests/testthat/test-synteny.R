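mk_pairs <- function(r1, r2) {
  data.frame(gene1 = sprintf("a%d", seq_along(r1)),
             gene2 = sprintf("b%d", seq_along(r1)),
             chrom1 = rep("c1", length(r1)), chrom2 = rep("c2", length(r1)),
             rank1 = r1, rank2 = r2, stringsAsFactors = FALSE)
}

test_that("consecutive collinear pairs chain into a single block", {
  bl <- chain_collinear_blocks(mk_pairs(0:4, 10:14), min_block_genes = 5)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_genes, 5L)
  expect_equal(bl$blocks$score, 250)
  expect_equal(bl$blocks$orientation, "same")
})

test_that("shuffled order breaks collinearity", {
  set.seed(9)
  bl <- chain_collinear_blocks(mk_pairs(0:4, sample(c(3, 0, 4, 1, 2))),
                               min_block_genes = 5)
  expect_equal(nrow(bl$blocks), 0L)
  expect_equal(nrow(chain_collinear_blocks(mk_pairs(integer(0),
                                                    integer(0)))$blocks), 0L)
})

test_that("an inverted run is chained in the inverted orientation", {
  bl <- chain_collinear_blocks(mk_pairs(0:4, c(20, 19, 18, 17, 16)),
                               min_block_genes = 5)
  expect_equal(bl$blocks$orientation, "inverted")
  expect_equal(bl$blocks$n_genes, 5L)
})

test_that("DP chain scores equal brute-force enumeration on toys", {
  cases <- list(
    mk_pairs(0:11, c(0:3, 7, 6, 5, 4, 8:11)),     # interior 4-gene inversion
    mk_pairs(c(0:5, 20:25), c(0:5, 2:7)),         # two separated runs
    mk_pairs(0:9, c(0, 2, 1, 4, 3, 6, 5, 8, 7, 9)) # noisy diagonal
  )
  for (pp in cases) {
    bl <- chain_collinear_blocks(pp, min_block_genes = 2)
    oracle <- brute_best_chain(pp)
    expect_equal(max(bl$blocks$score), oracle$score)
    top <- bl$members[bl$members$block_id ==
                        bl$blocks$block_id[which.max(bl$blocks$score)], ]
    idx <- sort(match(top$gene1, pp$gene1))
    expect_true(any(vapply(oracle$sets, identical, logical(1), idx)))
  }
})

test_that("chaining is symmetric in the two genomes", {
  pp <- mk_pairs(0:7, c(0, 1, 2, 5, 6, 7, 3, 4))
  fl <- data.frame(gene1 = pp$gene2, gene2 = pp$gene1, chrom1 = pp$chrom2,
                   chrom2 = pp$chrom1, rank1 = pp$rank2, rank2 = pp$rank1,
                   stringsAsFactors = FALSE)
  b1 <- chain_collinear_blocks(pp, min_block_genes = 2)
  b2 <- chain_collinear_blocks(fl, min_block_genes = 2)
  expect_equal(sort(b1$blocks$score), sort(b2$blocks$score))
  expect_equal(sort(b1$blocks$n_genes), sort(b2$blocks$n_genes))
})

test_that("anchor groups require the exact 1:2:4 ratio", {
  sim <- simulate_scenario(small_spec(seed = 2))
  syn <- synteny_anchor_groups(sim$genes)
  nfam <- length(unique(sim$genes$family[!sim$genes$single_copy]))
  expect_equal(nrow(syn$anchors$groups), nfam)
  # no gene in two groups
  expect_false(anyDuplicated(syn$anchors$members$gene) > 0)
  # deleting one octoploid copy excludes that family
  sim2 <- simulate_scenario(small_spec(
    copy_loss = data.frame(family = 2L, leaf = "oct_D"), seed = 2))
  syn2 <- synteny_anchor_groups(sim2$genes)
  expect_equal(nrow(syn2$anchors$groups), nfam - 1L)
  fam_of <- stats::setNames(sim2$genes$family, sim2$genes$gene)
  expect_false(any(fam_of[syn2$anchors$members$gene] == 2L))
  # empty blocks give an empty result
  expect_equal(nrow(extract_anchor_groups(NULL, sim$genes)$groups), 0L)
  # mismatched ratio names are a config error
  expect_error(extract_anchor_groups(syn$block_members, sim$genes,
                                     ratio = c(foo = 1, tet = 2, oct = 4)),
               "genome labels")
})

test_that("macro-synteny groups follow the chromosome tuple and threshold", {
  m <- data.frame(anchor_id = rep(c("a1", "a2", "a3"), each = 2),
                  chrom = c("c1", "c2", "c1", "c2", "c1", "c3"),
                  stringsAsFactors = FALSE)
  gr <- macro_synteny_groups(m, min_genes = 1)
  expect_equal(nrow(gr), 2L)
  expect_equal(gr$n_anchors[1], 2L)
  expect_equal(nrow(macro_synteny_groups(m, min_genes = 3)), 0L)
  sim <- simulate_scenario(small_spec(seed = 2))
  syn <- synteny_anchor_groups(sim$genes)
  gr2 <- macro_synteny_groups(syn$anchors$members, min_genes = 1)
  expect_equal(nrow(gr2), sim$spec$n_chromosomes)
  expect_equal(sum(gr2$n_anchors), nrow(syn$anchors$groups))
})
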