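# Consensus trees, Robinson-Foulds distances and outgroup rooting.

test_that("consensus of a singleton is the tree itself; disjoint trees give a star", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(topo_key(strict_consensus(list(tr))), topo_key(tr))
  t1 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t2 <- ape::read.tree(text = "(((A,C),E),(B,D));")
  star <- strict_consensus(list(t1, t2))
  expect_equal(length(karyotree:::tree_bipartitions(star)), 0)
})

test_that("strict and majority consensus match ape's consensus", {
  withr::local_seed(17)
  for (i in 1:5) {
    trees <- lapply(1:4, function(j) karyotree:::random_topology(paste0("t", 1:7)))
    s_mine <- strict_consensus(trees)
    class(trees) <- "multiPhylo"
    s_ape <- ape::consensus(trees, p = 1)
    expect_equal(
      sort(karyotree:::tree_bipartitions(s_mine)),
      sort(karyotree:::tree_bipartitions(s_ape))
    )
    m_mine <- majority_rule(trees, 0.5)
    m_ape <- ape::consensus(trees, p = 0.5)
    expect_equal(
      sort(karyotree:::tree_bipartitions(m_mine)),
      sort(karyotree:::tree_bipartitions(m_ape))
    )
  }
})

test_that("majority-rule node labels carry clade percentages", {
  t1 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t2 <- ape::read.tree(text = "(((A,B),D),(C,E));")
  t3 <- ape::read.tree(text = "(((A,B),E),(C,D));")
  maj <- majority_rule(list(t1, t2, t3), 0.5)
  expect_true("100" %in% maj$node.label) # the A|B clade in all three
})

test_that("robinson_foulds: identical 0, alternative quartets 2, leaf mismatch errors", {
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(q1, q1), 0)
  expect_equal(robinson_foulds(q1, q2), 2)
  q3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(q1, q3), "leaf set")
})

test_that("robinson_foulds matches phangorn on random tree pairs", {
  skip_if_not_installed("phangorn")
  withr::local_seed(19)
  for (i in 1:100) {
    a <- karyotree:::random_topology(paste0("t", 1:8))
    b <- karyotree:::random_topology(paste0("t", 1:8))
    expect_equal(robinson_foulds(a, b), as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("outgroup rooting splits ingroup from outgroup", {
  q <- ape::read.tree(text = "((A,B),(G,T));")
  r <- root_on_outgroup(q, c("G", "T"))
  expect_true(ape::is.rooted(r))
  kids <- karyotree:::tips_below(r, r$edge[r$edge[, 1] == length(r$tip.label) + 1, 2][1])
  expect_true(setequal(kids, c("G", "T")) || setequal(kids, c("A", "B")))
  # single-leaf outgroup roots on its pendant edge
  r1 <- root_on_outgroup(q, "G")
  expect_true(ape::is.rooted(r1))
  expect_error(root_on_outgroup(q, c("A", "B", "G", "T")), "entire leaf set")
})

test_that("non-monophyletic outgroups root on the closest edge with a warning", {
  tr <- ape::read.tree(text = "(((A,G),B),(C,T));")
  expect_warning(r <- root_on_outgroup(tr, c("G", "T")), "not monophyletic")
  expect_true(ape::is.rooted(r))
})

test_that("compare_trees reports rf and the shared clades", {
  tr <- ape::read.tree(text = "((((AHY,PFR),(AMA,ACH)),MMO),(AAE,(GGA,TRU)));")
  self <- compare_trees(tr, tr)
  expect_equal(self$rf, 0)
  broken <- ape::read.tree(text = "((((AHY,PFR),(AMA,MMO)),ACH),(AAE,(GGA,TRU)));")
  cmp <- compare_trees(tr, broken)
  expect_gt(cmp$rf, 0)
  shared_keys <- vapply(cmp$shared_clades, karyotree:::clade_key, "")
  expect_true(karyotree:::clade_key(c("AHY", "PFR")) %in% shared_keys)
  expect_false(karyotree:::clade_key(c("AMA", "ACH")) %in% shared_keys)
})
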