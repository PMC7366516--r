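# Homology-map parsing, label conversion and event detection.

test_that("PAK/GGA label conversion follows the fixed table and round-trips", {
  tab <- pak_gga_table()
  expect_equal(nrow(tab), 15)
  expect_equal(tab$gga_chr[tab$pak == "PAK4"], "GGA4")
  expect_equal(tab$gga_region[tab$pak == "PAK4"], "q")
  expect_equal(tab$gga_chr[tab$pak == "PAK10"], "GGA4")
  expect_equal(tab$gga_region[tab$pak == "PAK10"], "p")
  expect_equal(tab$gga_chr[tab$pak == "PAK12"], "GGA11")
  expect_equal(tab$gga_chr[tab$pak == "PAK15"], "GGA14")

  mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
  pak <- convert_ancestral_scheme(mmo, "PAK")
  # GGA4q rows become PAK4, GGA4p rows PAK10
  expect_true(all(pak$ancestral_chr[mmo$ancestral_chr == "GGA4" &
    mmo$ancestral_region == "q"] == "PAK4"))
  expect_true(all(pak$ancestral_chr[mmo$ancestral_chr == "GGA4" &
    mmo$ancestral_region == "p"] == "PAK10"))
  back <- convert_ancestral_scheme(pak, "GGA")
  expect_equal(back$ancestral_chr, mmo$ancestral_chr)
  expect_equal(back$ancestral_region, mmo$ancestral_region)
})

test_that("the packaged MMO painting map parses with its printed shape", {
  mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
  expect_s3_class(mmo, "homology_map")
  expect_equal(unique(mmo$taxon), "MMO")
  expect_equal(unique(mmo$diploid_number), 48L)
  # "Number of pairs" column of the transcription
  expect_equal(count_descendant_pairs(mmo, "GGA1"), 4)
  expect_equal(count_descendant_pairs(mmo, "GGA2"), 3)
  expect_equal(count_descendant_pairs(mmo, "GGA5"), 1)
  expect_equal(count_descendant_pairs(mmo, "GGA99"), 0) # absent, not an error
})

test_that("parse errors name the offending line and rule", {
  dir <- withr::local_tempdir()
  hdr <- "taxon\tancestral_chr\tancestral_region\tdescendant_chr\tdescendant_region\tevidence\tdiploid_number"
  bad_region <- file.path(dir, "bad_region.tsv")
  writeLines(c(hdr, "X\tGGA1\tbanana\tX1\twhole\tBAC\t48"), bad_region)
  expect_error(parse_homology_tsv(bad_region), "line 1.*region")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c(
    hdr,
    "X\tGGA1\twhole\tX1\twhole\tBAC\t48",
    "X\tGGA1\twhole\tX1\twhole\tBAC\t48"
  ), dup)
  expect_error(parse_homology_tsv(dup), "duplicate")

  odd <- file.path(dir, "odd.tsv")
  writeLines(c(hdr, "X\tGGA1\twhole\tX1\twhole\tBAC\t47"), odd)
  expect_error(parse_homology_tsv(odd), "diploid")

  empty <- file.path(dir, "empty.tsv")
  writeLines(hdr, empty)
  expect_warning(m <- parse_homology_tsv(empty), "no assignments")
  expect_equal(nrow(m), 0)
})

test_that("homology maps round-trip through TSV exactly", {
  mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_homology_tsv(mmo, path)
  again <- parse_homology_tsv(path)
  expect_equal(as.data.frame(again), as.data.frame(mmo))
})

test_that("fusion detection recovers the printed syntenic associations", {
  mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
  fus <- detect_fusions(mmo)
  parts <- setNames(fus$participants, fus$locus)
  expect_equal(parts[["MMO3"]], c("GGA1", "GGA2"))
  expect_equal(parts[["MMO7"]], c("GGA3", "GGA4"))
  expect_equal(parts[["MMO8"]], c("GGA8", "GGA9"))
  expect_equal(parts[["MMO13"]], c("GGA13", "GGA2"))
  # loci come out in ascending descendant chromosome order
  expect_equal(fus$locus, fus$locus[order(karyotree:::descendant_number(fus$locus))])
})

test_that("fission detection reports each split chromosome with its count", {
  mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
  fis <- detect_fissions(mmo)
  counts <- setNames(fis$n_descendants, fis$ancestral_chr)
  expect_equal(counts[["GGA1"]], 4L)
  expect_equal(counts[["GGA3"]], 2L)
  expect_equal(sort(fis$descendants[[which(fis$ancestral_chr == "GGA3")]]),
    c("MMO5", "MMO7"))
})

test_that("one-to-one maps yield no events", {
  gga <- parse_homology_tsv(karyotree_example("table5_all_species.tsv"))
  gga <- gga[gga$taxon == "GGA", ]
  # chicken chromosome 4 is itself a fused PAK4/PAK10 - drop it to get a
  # strictly one-to-one map
  id <- karyotree:::new_homology_map(gga[gga$ancestral_chr != "GGA4", ])
  expect_equal(nrow(detect_fusions(id)), 0)
  expect_equal(nrow(detect_fissions(id)), 0)
  expect_equal(count_descendant_pairs(id, "GGA5"), 1)
})

test_that("descendant count totals exceed assigned ancestors exactly when fissions exist", {
  for (tx in c("MMO", "AHY", "AAE", "GGA")) {
    all5 <- parse_homology_tsv(karyotree_example("table5_all_species.tsv"))
    m <- karyotree:::new_homology_map(all5[all5$taxon == tx, ])
    counts <- descendant_pair_counts(m)
    n_anc <- length(unique(m$ancestral_chr))
    expect_gte(sum(counts$n_descendants), n_anc)
    expect_identical(
      sum(counts$n_descendants) == n_anc,
      nrow(detect_fissions(m)) == 0
    )
  }
})
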