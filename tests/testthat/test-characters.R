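# Character enumeration, scoring, matrix construction and editing.

test_that("enumeration finds the named associations in the study maps", {
  chars <- enumerate_characters(study_maps())
  keys <- vapply(chars$units, paste, "", collapse = "+")
  # the macaw-defining PAK1/PAK4 association and the near-universal
  # PAK6/PAK7 and PAK8/PAK9 associations
  expect_true("PAK1+PAK4" %in% keys[chars$kind == "fusion-association"])
  expect_true("PAK6+PAK7" %in% keys[chars$kind == "fusion-association"])
  expect_true("PAK8+PAK9" %in% keys[chars$kind == "fusion-association"])
  # fusions come before fissions, ordered by lowest participant
  expect_false(is.unsorted(match(chars$kind, c("fusion-association", "fission-pattern"))))
  for (k in unique(chars$kind)) {
    first <- vapply(chars$units[chars$kind == k], function(u) {
      min(karyotree:::unit_sort_key(u))
    }, 1L)
    expect_false(is.unsorted(first))
  }
})

test_that("identical one-to-one maps give an empty character list", {
  maps <- tibble::tibble(
    taxon = rep(c("X", "Y"), each = 3),
    ancestral_chr = rep(paste0("GGA", 1:3), 2),
    ancestral_region = "whole",
    descendant_chr = rep(paste0("C", 1:3), 2),
    descendant_region = "whole",
    evidence = "inferred",
    diploid_number = 6L
  )
  chars <- enumerate_characters(karyotree:::new_homology_map(maps))
  expect_equal(nrow(chars), 0)
})

test_that("a single differing fusion yields exactly one character", {
  # note: GGA4 is avoided because the chicken chromosome 4 is itself a
  # PAK4/PAK10 fusion and would contribute an association of its own
  base <- tibble::tibble(
    taxon = "X",
    ancestral_chr = paste0("GGA", c(1, 2, 3, 5, 6)), ancestral_region = "whole",
    descendant_chr = paste0("C", 1:5), descendant_region = "whole",
    evidence = "inferred", diploid_number = 10L
  )
  fused <- base
  fused$taxon <- "Y"
  fused$descendant_chr[3] <- "C2" # GGA2 and GGA3 share one chromosome in Y
  fused$diploid_number <- 8L
  maps <- karyotree:::new_homology_map(dplyr::bind_rows(base, fused))
  chars <- enumerate_characters(maps)
  expect_equal(nrow(chars), 1)
  expect_equal(chars$kind, "fusion-association")
  expect_equal(chars$units[[1]], c("PAK2", "PAK3"))
  expect_warning(m <- build_matrix(maps), "2 taxa")
  expect_equal(unname(m$states["Y", 1]), 1L)
  expect_equal(unname(m$states["X", 1]), 0L)
})

test_that("scoring implements presence / absence / missing", {
  maps <- study_maps()
  chars <- enumerate_characters(maps)
  pak89 <- chars[vapply(chars$units, function(u) identical(u, c("PAK8", "PAK9")), TRUE), ]
  mmo <- karyotree:::new_homology_map(maps[maps$taxon == "MMO", ])
  aae <- karyotree:::new_homology_map(maps[maps$taxon == "AAE", ])
  expect_equal(score_taxon(mmo, pak89), 1L) # fused on MMO8
  expect_equal(score_taxon(aae, pak89), 0L) # both assigned, not associated
  # a character involving an unassigned chromosome scores missing: AMA has
  # no GGA10 (PAK11) assignment
  ama <- karyotree:::new_homology_map(maps[maps$taxon == "AMA", ])
  pak11 <- chars[vapply(chars$units, function(u) "PAK11" %in% u, TRUE), ][1, ]
  expect_true(is.na(score_taxon(ama, pak11)))
})

test_that("the study matrix scores the macaw association as printed", {
  m <- build_matrix(study_maps())
  col <- m$states[, "F.PAK1+PAK4"]
  expect_equal(unname(col[c("AHY", "ACH", "PFR", "AMA")]), rep(1L, 4))
  expect_equal(unname(col["GGA"]), 0L)
  expect_equal(unname(col["TRU"]), 0L)
})

test_that("build_matrix is invariant to the order maps are supplied in", {
  maps <- study_maps()
  m1 <- build_matrix(maps)
  rev_maps <- karyotree:::new_homology_map(maps[rev(seq_len(nrow(maps))), ])
  m2 <- build_matrix(rev_maps)
  expect_equal(colnames(m1$states), colnames(m2$states))
  expect_equal(
    m1$states[sort(m1$taxa), , drop = FALSE],
    m2$states[sort(m2$taxa), , drop = FALSE]
  )
})

test_that("classification partitions characters and matches the definition", {
  st <- rbind(
    c(1L, 1L, 1L, NA),
    c(1L, 0L, 1L, NA),
    c(0L, 0L, 1L, 1L),
    c(0L, 0L, NA, 1L),
    c(0L, 0L, 1L, 1L),
    c(0L, 0L, 1L, 1L),
    c(0L, 0L, 1L, 1L),
    c(0L, 0L, 1L, 1L)
  )
  rownames(st) <- paste0("t", 1:8)
  m <- char_matrix(st)
  cls <- classify_characters(m)$class
  expect_equal(cls, c(
    "parsimony-informative", # 1,1,0... both states twice
    "autapomorphic/uninformative", # single 1
    "constant", # 1s and missing only
    "constant"
  ))
  g <- glance(m)
  expect_equal(g$n_informative + g$n_uninformative + g$n_constant, g$n_characters)
})

test_that("drop_character removes one column and leaves the input alone", {
  m <- build_matrix(study_maps())
  n0 <- ncol(m$states)
  d <- drop_character(m, "F.PAK8+PAK9")
  expect_equal(ncol(d$states), n0 - 1)
  expect_false("F.PAK8+PAK9" %in% colnames(d$states))
  expect_true("F.PAK8+PAK9" %in% colnames(m$states)) # original unchanged
  expect_error(drop_character(m, "nope"), "no character")
  # dropping every column one at a time always leaves n-1 columns
  for (id in colnames(m$states)) {
    expect_equal(ncol(drop_character(m, id)$states), n0 - 1)
  }
})

test_that("pairwise decomposition splits multi-chromosome associations", {
  maps <- study_maps()
  whole <- enumerate_characters(maps)
  pairs <- enumerate_characters(maps, pairwise = TRUE)
  triple <- whole$units[vapply(whole$units, length, 1L) == 3]
  expect_gt(length(triple), 0)
  expect_true(all(vapply(pairs$units[pairs$kind == "fusion-association"],
    length, 1L) == 2))
})

test_that("tidy and autoplot views of a matrix agree with its cells", {
  m <- build_matrix(study_maps())
  long <- tidy(m)
  expect_equal(nrow(long), prod(dim(m)))
  expect_equal(
    long$state[long$taxon == "MMO" & long$character == "F.PAK1+PAK2"], "1"
  )
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
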