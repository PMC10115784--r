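test_that("JC distances follow the closed form and saturation cap", {
  # two 10-site rows with 3 mismatches: p = 0.3
  aln <- c(a = "AAAAAAAAAA", b = "CCCAAAAAAA")
  D <- jc_distance_matrix(aln)
  expect_equal(D["a", "b"], -0.75 * log(1 - 0.4))
  expect_equal(diag(D), c(a = 0, b = 0))
  expect_true(isSymmetric(D))
  expect_equal(jc_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_warning(Ds <- jc_distance_matrix(c(a = "AAAA", b = "CCCC")),
                 "saturated")
  expect_equal(Ds["a", "b"], 5.0)
  # gapped sites are excluded from the shared-site count: 10 shared
  # sites, 3 mismatches
  Dg <- jc_distance_matrix(c(a = "A-AAAAAAAAA", b = "ACCCCAAAAAA"))
  expect_equal(Dg["a", "b"], -0.75 * log(1 - 0.4))
})

test_that("random matrices give symmetric non-negative distances", {
  set.seed(1)
  for (i in 1:5) {
    rows <- vapply(1:4, function(j)
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
      character(1))
    D <- suppressWarnings(jc_distance_matrix(stats::setNames(rows,
                                                             letters[1:4])))
    expect_true(isSymmetric(D))
    expect_true(all(D >= 0))
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  add <- random_additive_matrix(5, seed = 10)
  tr <- nj_tree(add$D)
  expect_equal(ape::dist.topo(ape::unroot(tr), add$tree), 0,
               ignore_attr = TRUE)
  # property: recovery on 50 random 6-taxon additive matrices
  fails <- 0
  for (s in 1:50) {
    add6 <- random_additive_matrix(6, seed = 100 + s)
    tr6 <- nj_tree(add6$D)
    if (ape::dist.topo(ape::unroot(tr6), add6$tree) != 0) fails <- fails + 1
  }
  expect_equal(fails, 0)
  # 3 taxa: the unique unrooted tree
  D3 <- matrix(c(0, 1, 2, 1, 0, 1.5, 2, 1.5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ape::Ntip(nj_tree(D3)), 3L)
  bad <- D3
  bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports are 100 for conflict-free alignments", {
  sim <- simulate_scenario(small_spec(seed = 3, exchanges = NULL,
                                      n_gene_families = 6L))
  g <- sim$genes[sim$genes$family == 1L, ]
  aln <- stats::setNames(g$cds, g$leaf)
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  tr2 <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  expect_identical(tr$node.label, tr2$node.label)
  expect_null(bootstrap_support(aln, n_replicates = 0)$node.label)
  # a clean 4-taxon alignment where every site supports the same split
  aln4 <- c(a = strrep("A", 40), b = strrep("A", 40),
            c = strrep("C", 40), d = strrep("C", 40))
  tr4 <- bootstrap_support(aln4, n_replicates = 100, seed = 1)
  sup4 <- suppressWarnings(as.numeric(tr4$node.label))
  expect_true(all(sup4[!is.na(sup4)] == 100))
})

test_that("quartet species tree maximizes shared quartets exhaustively", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  taxa <- c("a", "b", "c", "d")
  maj <- quartet_species_tree(list(t1, t1, t1, t2), taxa)
  expect_true(ape::all.equal.phylo(ape::unroot(maj), ape::unroot(t1),
                                   use.edge.length = FALSE))
  expect_equal(attr(maj, "score"), 3)
  # all trees identical: perfect score n_genes * choose(n, 4)
  t5 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  best <- quartet_species_tree(list(t5, t5), c("a", "b", "c", "d", "e"))
  expect_equal(attr(best, "score"), attr(best, "max_score"))
  expect_true(ape::all.equal.phylo(ape::unroot(best), ape::unroot(t5),
                                   use.edge.length = FALSE))
  # optimality: returned score >= every enumerated alternative
  gts <- list(t5, t5, ape::read.tree(text = "((a,c),(b,(d,e)));"))
  got <- quartet_species_tree(gts, c("a", "b", "c", "d", "e"))
  cands <- phangorn::allTrees(5, rooted = FALSE,
                              tip.label = c("a", "b", "c", "d", "e"))
  scores <- vapply(cands, function(tr) {
    sum(vapply(gts, function(g)
      sum(allorigin:::quartet_states(g, c("a", "b", "c", "d", "e")) ==
            allorigin:::quartet_states(tr, c("a", "b", "c", "d", "e"))),
      numeric(1)))
  }, numeric(1))
  expect_equal(attr(got, "score"), max(scores))
  expect_error(quartet_species_tree(list(t1), letters[1:9]), "8 taxa")
})
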