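# The karyotype evolution simulator.

test_that("the default template is a PAK-like 2n = 80 complement", {
  tpl <- ancestral_template()
  expect_equal(tpl$diploid_number, 80L)
  expect_equal(sum(startsWith(tpl$labels, "PAK")), 15)
  expect_equal(sum(startsWith(tpl$labels, "MIC")), 25)
})

test_that("zero rates give identity maps with the template diploid number", {
  expect_warning(mod <- evolution_model(0, 0, 0), "degenerate")
  sim <- simulate_karyotypes(sim_study_tree(), model = mod, seed = 1)
  expect_equal(nrow(sim$event_log), 0)
  expect_true(all(sim$maps$diploid_number == 80L))
  expect_equal(nrow(detect_fusions(sim$maps)), 0)
  expect_equal(nrow(detect_fissions(sim$maps)), 0)
  expect_equal(ncol(truth_matrix(sim)$states), 0)
})

test_that("diploid numbers obey 2n = 80 - 2 fusions + 2 fissions along each path", {
  for (s in 1:5) {
    sim <- simulate_karyotypes(sim_study_tree(), seed = s)
    log <- sim$event_log[sim$event_log$applied, ]
    for (tx in names(sim$tip_states)) {
      tip <- which(sim$tree$tip.label == tx)
      onpath <- vapply(seq_len(nrow(log)), function(j) {
        tx %in% karyotree:::tips_below(sim$tree, log$node[j])
      }, TRUE)
      nf <- sum(log$kind[onpath] == "fusion")
      ns <- sum(log$kind[onpath] == "fission")
      expect_equal(
        unique(sim$maps$diploid_number[sim$maps$taxon == tx]),
        80L - 2L * nf + 2L * ns
      )
    }
  }
})

test_that("simulations are reproducible under a fixed seed", {
  a <- simulate_karyotypes(sim_study_tree(), seed = 99)
  b <- simulate_karyotypes(sim_study_tree(), seed = 99)
  expect_identical(a$maps, b$maps)
  expect_identical(a$event_log, b$event_log)
})

test_that("replaying the event log reproduces every tip karyotype exactly", {
  for (s in c(2, 12, 31)) {
    sim <- simulate_karyotypes(sim_study_tree(), seed = s)
    expect_identical(replay_events(sim), sim$tip_states)
  }
})

test_that("trees without branch lengths or with non-binary shape are refused", {
  tr <- sim_study_tree()
  tr$edge.length <- NULL
  expect_error(simulate_karyotypes(tr, seed = 1), "branch lengths")
  expect_error(
    simulate_karyotypes(ape::unroot(sim_study_tree()), seed = 1),
    "rooted binary"
  )
})

test_that("per-branch event counts match their Poisson expectation", {
  # two-tip tree: one branch of length 4 per tip; average applied + skipped
  # counts over many seeded runs sit within 3 standard errors of rate x length
  tr <- ape::read.tree(text = "(a:4,b:4);")
  nrun <- 300
  tot <- c(fusion = 0, fission = 0, inversion = 0)
  for (s in seq_len(nrun)) {
    sim <- simulate_karyotypes(tr, seed = s)
    tot <- tot + table(factor(sim$event_log$kind,
      levels = c("fusion", "fission", "inversion")))
  }
  mean_counts <- tot / (2 * nrun) # two branches per run
  expected <- c(fusion = 0.5, fission = 0.5, inversion = 0.25) * 4
  se <- sqrt(expected / (2 * nrun))
  for (k in names(expected)) {
    expect_lt(abs(mean_counts[[k]] - expected[[k]]), 3 * se[[k]])
  }
})

test_that("truth matrix columns are the clades subtended by each event", {
  sim <- simulate_karyotypes(sparse_sim_tree(), seed = 5)
  tm <- truth_matrix(sim)
  log <- sim$event_log[sim$event_log$applied &
    sim$event_log$kind %in% c("fusion", "fission"), ]
  expect_equal(ncol(tm$states), nrow(log))
  for (j in seq_len(nrow(log))) {
    clade <- karyotree:::tips_below(sim$tree, log$node[j])
    expect_equal(
      sort(rownames(tm$states)[tm$states[, j] == 1L]),
      sort(clade)
    )
  }
})

test_that("homoplasy-free histories code to clade characters: CI 1 on the true tree", {
  for (s in 1:5) {
    sim <- simulate_karyotypes(sim_study_tree(), seed = 100 + s)
    tm <- truth_matrix(sim)
    len <- fitch_length(ape::unroot(sim$tree), tm)
    expect_equal(len, sum(karyotree:::min_steps(tm)))
    expect_equal(tree_statistics(len, tm)$ci, 1)
  }
})

test_that("auto-coding matches the truth matrix column-for-column when events do not interact", {
  tr <- sparse_sim_tree()
  n_free <- 0
  for (s in 1:10) {
    sim <- simulate_karyotypes(tr, seed = s)
    if (events_interaction_free(sim)) {
      n_free <- n_free + 1
      expect_equal(
        column_signatures(build_matrix(sim$maps)),
        column_signatures(truth_matrix(sim)),
        info = paste("seed", s)
      )
    }
  }
  expect_gte(n_free, 7)
})

test_that("detection on round-tripped simulated maps equals the replayed states", {
  for (s in c(3, 9)) {
    sim <- simulate_karyotypes(sim_study_tree(), seed = s)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_homology_tsv(sim$maps, path)
    maps <- parse_homology_tsv(path)
    det_f <- detect_fusions(maps)
    det_s <- detect_fissions(maps)
    exp <- expected_events_from_states(replay_events(sim))
    for (tx in names(sim$tip_states)) {
      got <- vapply(det_f$participants[det_f$taxon == tx], paste, "",
        collapse = "+")
      want <- vapply(exp$fus[[tx]], paste, "", collapse = "+")
      expect_setequal(got, want)
      gs <- setNames(det_s$n_descendants[det_s$taxon == tx],
        det_s$ancestral_chr[det_s$taxon == tx])
      ws <- exp$fis[[tx]]
      expect_setequal(names(gs), names(ws))
      expect_equal(unname(gs[names(ws)]), unname(as.integer(ws)))
    }
  }
})
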