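roles5 <- c(o = "O", t = "T1", u = "T2", p = "P1", q = "P2")

test_that("canonical form is invariant under sibling order", {
  tr1 <- ape::read.tree(text = "((o,(t,p)),q);")
  tr2 <- ape::read.tree(text = "(q,((p,t),o));")
  s1 <- canonicalize_topology(tr1, roles5[c("o", "t", "p", "q")])
  s2 <- canonicalize_topology(tr2, roles5[c("o", "t", "p", "q")])
  expect_identical(s1, s2)
  tr3 <- ape::read.tree(text = "((o,t),(p,q));")
  expect_false(identical(
    canonicalize_topology(tr3, roles5[c("o", "t", "p", "q")]), s1))
  expect_error(canonicalize_topology(tr1, roles5["o"]), "unmapped")
})

test_that("all 105 rooted 5-tip topologies canonicalize distinctly", {
  trees <- enumerate_rooted(unname(roles5))
  expect_length(trees, 105L)
  strs <- vapply(trees, function(tr) allorigin:::canon_nested(tr)$str,
                 character(1))
  expect_equal(length(unique(strs)), 105L)
  # idempotence: parsing a canonical string back and re-canonicalizing
  # returns the same string
  for (s in strs[c(1, 50, 105)]) {
    tr <- ape::read.tree(text = paste0(s, ";"))
    roles <- stats::setNames(tr$tip.label, tr$tip.label)
    expect_identical(canonicalize_topology(tr, roles), s)
  }
})

test_that("model class sets contain the expected shapes and are disjoint", {
  wgd <- model_predicted_classes("WGD")
  ret <- model_predicted_classes("reticulate")
  expect_length(wgd, 6L)
  expect_length(ret, 48L)
  expect_length(intersect(wgd, ret), 0L)
  roles <- default_roles()
  # WGD shape: sister pairs of octoploid homoeologs under each tetraploid
  # subgenome
  tr_wgd <- ape::read.tree(
    text = "(out,((tet_A,(oct_A,oct_B)),(tet_C,(oct_C,oct_D))));")
  expect_true(canonicalize_topology(tr_wgd, roles) %in% wgd)
  # reticulate shape: tetraploid-octoploid ortholog cherries
  tr_ret <- ape::read.tree(
    text = "(out,((((tet_A,oct_A),oct_B),(tet_C,oct_C)),oct_D));")
  expect_true(canonicalize_topology(tr_ret, roles) %in% ret)
  expect_false(canonicalize_topology(tr_wgd, roles) %in% ret)
  expect_error(model_predicted_classes("banana"))
})

test_that("census counts classes, ranks them and conserves the total", {
  roles <- default_roles()
  tr_ret <- ape::read.tree(
    text = "(out,((((tet_A,oct_A),oct_B),(tet_C,oct_C)),oct_D));")
  tr_wgd <- ape::read.tree(
    text = "(out,((tet_A,(oct_A,oct_B)),(tet_C,(oct_C,oct_D))));")
  cen <- census(c(rep(list(tr_ret), 7), rep(list(tr_wgd), 3)), roles)
  expect_equal(cen$total, 10L)
  expect_equal(sum(cen$classes$count), 10L)
  expect_equal(sum(cen$classes$fraction), 1)
  expect_equal(cen$classes$count[1], 7L)
  expect_equal(cen$classes$model[1], "reticulate-model")
  expect_equal(cen$verdict, "reticulate-model")
  one <- census(rep(list(tr_wgd), 10), roles)
  expect_equal(nrow(one$classes), 1L)
  expect_equal(one$classes$fraction, 1)
  expect_equal(one$verdict, "WGD-model")
})

test_that("multifurcating trees are counted but never model-tagged", {
  roles <- default_roles()
  tr_poly <- ape::read.tree(
    text = "(out,(tet_A,tet_C,oct_A,oct_B,oct_C,oct_D));")
  cen <- census(list(tr_poly), roles)
  expect_equal(cen$classes$model, "other")
})
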