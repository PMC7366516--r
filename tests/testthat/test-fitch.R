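# Fitch counting against brute-force enumeration and its invariances.

test_that("quartet worked example: lengths 1 and 2", {
  m <- char_matrix(matrix(c(1L, 1L, 0L, 0L), 4, 1,
    dimnames = list(c("A", "B", "C", "D"), "c1")))
  grouped <- ape::read.tree(text = "((A,B),(C,D));")
  alt1 <- ape::read.tree(text = "((A,C),(B,D));")
  alt2 <- ape::read.tree(text = "((A,D),(B,C));")
  expect_equal(fitch_length(grouped, m), 1)
  expect_equal(fitch_length(alt1, m), 2)
  expect_equal(fitch_length(alt2, m), 2)
})

test_that("fitch agrees with brute-force enumeration on random instances", {
  withr::local_seed(123)
  for (i in 1:60) {
    n <- sample(4:7, 1)
    taxa <- paste0("t", seq_len(n))
    phy <- karyotree:::random_topology(taxa)
    col <- sample(c(0L, 1L, NA_integer_), n, replace = TRUE,
      prob = c(0.4, 0.4, 0.2))
    if (all(is.na(col))) col[1] <- 1L
    m <- char_matrix(matrix(col, n, 1, dimnames = list(taxa, "c")))
    expect_equal(
      fitch_length(phy, m),
      brute_force_fitch(phy, setNames(col, taxa)),
      info = paste("case", i)
    )
  }
})

test_that("fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  withr::local_seed(99)
  for (i in 1:20) {
    m <- random_binary_matrix(8, 25, p_missing = 0.1)
    phy <- karyotree:::random_topology(m$taxa)
    dat <- phangorn::phyDat(
      ifelse(is.na(m$states), "?", as.character(m$states)),
      type = "USER", levels = c("0", "1"), ambiguity = "?"
    )
    expect_equal(
      fitch_length(phy, m),
      as.integer(phangorn::parsimony(phy, dat, method = "fitch"))
    )
  }
})

test_that("fitch length ignores rooting and relabels consistently", {
  withr::local_seed(5)
  m <- random_binary_matrix(7, 15)
  phy <- karyotree:::random_topology(m$taxa)
  base <- fitch_length(phy, m)
  for (og in m$taxa[1:4]) {
    expect_equal(fitch_length(ape::root(phy, og, resolve.root = TRUE), m), base)
  }
  # permuting leaf labels together with matrix rows changes nothing
  perm <- sample(m$taxa)
  phy2 <- phy
  phy2$tip.label <- perm[match(phy$tip.label, m$taxa)]
  m2 <- char_matrix(m$states[m$taxa, , drop = FALSE])
  rownames(m2$states) <- perm
  m2 <- char_matrix(m2$states)
  expect_equal(fitch_length(phy2, m2), base)
})

test_that("an all-constant matrix has length zero on any tree", {
  st <- matrix(1L, 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  m <- char_matrix(st)
  withr::local_seed(1)
  expect_equal(fitch_length(karyotree:::random_topology(m$taxa), m), 0)
})

test_that("statistics identities: ci + hi = 1 and L = sum of observed steps", {
  withr::local_seed(11)
  for (i in 1:10) {
    m <- random_binary_matrix(6, 12, p_missing = 0.1)
    res <- exhaustive_search(m)
    expect_equal(res$ci + res$hi, 1)
    expect_equal(sum(res$per_character$observed_steps), res$length)
    stats <- tree_statistics(res, m)
    expect_equal(stats$ci, res$ci)
  }
  # single variable character with 2 observed steps on a fixed tree: ci 1/2
  m <- char_matrix(matrix(c(1L, 0L, 1L, 0L), 4, 1,
    dimnames = list(c("A", "B", "C", "D"), "c")))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, m), 2)
  expect_equal(tree_statistics(2L, m)$ci, 0.5)
})

test_that("dropping a variable character never increases tree length", {
  withr::local_seed(21)
  m <- random_binary_matrix(6, 15)
  phy <- karyotree:::random_topology(m$taxa)
  base <- fitch_length(phy, m)
  for (id in colnames(m$states)[1:8]) {
    expect_lte(fitch_length(phy, drop_character(m, id)), base)
  }
})

test_that("zero-length searches define CI = 1 by convention", {
  st <- matrix(1L, 4, 3, dimnames = list(c("A", "B", "C", "D"), NULL))
  m <- char_matrix(st)
  expect_message(res <- exhaustive_search(m), "convention")
  expect_equal(res$ci, 1)
  expect_equal(res$hi, 0)
  expect_true(is.na(res$ri))
})
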