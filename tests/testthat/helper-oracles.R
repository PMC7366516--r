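# Independent oracles and generators used across the suite. Everything
# here is deliberately naive - enumeration and brute force - so it shares
# no code with the implementation it checks.

# Brute-force Fitch: minimise changed edges over all assignments of
# internal nodes (and missing leaves) to {0, 1}.
brute_force_fitch <- function(phy, states) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  nint <- phy$Nnode
  total <- n + nint
  fixed <- rep(NA_integer_, total)
  fixed[seq_len(n)] <- states[phy$tip.label]
  vars <- which(is.na(fixed))
  e <- phy$edge
  best <- Inf
  for (bits in 0:(2^length(vars) - 1)) {
    s <- fixed
    if (length(vars) > 0) {
      s[vars] <- bitwAnd(bits %/% 2^(seq_along(vars) - 1), 1L)
    }
    len <- sum(s[e[, 1]] != s[e[, 2]])
    best <- min(best, len)
  }
  best
}

# Random binary matrix over given taxa.
random_binary_matrix <- function(ntaxa, nchar, p_missing = 0) {
  st <- matrix(sample(0:1, ntaxa * nchar, replace = TRUE), ntaxa, nchar,
    dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  if (p_missing > 0) {
    st[runif(length(st)) < p_missing] <- NA_integer_
  }
  # ensure every column has an observed state
  for (j in seq_len(nchar)) {
    if (all(is.na(st[, j]))) st[1, j] <- 1L
  }
  char_matrix(st)
}

# Canonical topology key of a phylo.
topo_key <- function(phy) {
  paste(sort(karyotree:::tree_bipartitions(phy)), collapse = ";")
}

topo_keys <- function(trees) sort(vapply(unclass(trees), topo_key, ""))

# All unrooted topologies over taxa, as phylo objects (tiny n only).
all_topologies <- function(taxa) {
  n <- length(taxa)
  encs <- karyotree:::enumerate_topologies(n)
  lapply(seq_len(nrow(encs)), function(i) {
    karyotree:::decode_tree(encs[i, ], taxa)
  })
}

# Independent TBR adjacency test: Tp is one TBR move away from T iff some
# edge-induced bipartition (A, B) of T is also an edge of Tp and the two
# trees agree when restricted to A and to B (ape::keep.tip does the
# restriction).
restricted_equal <- function(a, b, tips) {
  if (length(tips) < 4) return(TRUE)
  ra <- ape::keep.tip(a, tips)
  rb <- ape::keep.tip(b, tips)
  identical(topo_key(ra), topo_key(rb))
}

tbr_adjacent_oracle <- function(t1, t2) {
  if (identical(topo_key(t1), topo_key(t2))) return(FALSE)
  taxa <- t1$tip.label
  splits <- c(
    lapply(karyotree:::tree_bipartitions(t1), function(k) {
      strsplit(k, "|", fixed = TRUE)[[1]]
    }),
    as.list(taxa) # pendant-edge splits
  )
  k2 <- c(karyotree:::tree_bipartitions(t2),
    vapply(taxa, karyotree:::clade_key, ""))
  for (A in splits) {
    B <- setdiff(taxa, A)
    keyA <- karyotree:::clade_key(A)
    keyB <- karyotree:::clade_key(B)
    if (!(keyA %in% k2 || keyB %in% k2 || length(A) == 1)) next
    if (restricted_equal(t1, t2, A) && restricted_equal(t1, t2, B)) {
      return(TRUE)
    }
  }
  FALSE
}

# Simulation helpers -----------------------------------------------------

sparse_sim_tree <- function(scale = 0.2) {
  tr <- sim_study_tree()
  tr$edge.length <- tr$edge.length * scale
  tr
}

# Per-tip fusion sets and fission counts derived directly from replayed
# genome states (a different path than TSV emission + detection).
expected_events_from_states <- function(states) {
  fus <- list()
  fis <- list()
  for (tx in names(states)) {
    sets <- lapply(states[[tx]], function(ch) sort(unique(ch$anc)))
    fus[[tx]] <- Filter(function(s) length(s) >= 2, sets)
    cnt <- table(unlist(lapply(sets, unique)))
    fis[[tx]] <- cnt[cnt >= 2]
  }
  list(fus = fus, fis = fis)
}

# TRUE when no two simulated events interact in a way that makes the
# cumulative character coding non-identifiable: all fissions of one
# ancestral chromosome lie on a single root-to-tip chain, and no two
# overlapping fusions subtend the same tip set.
events_interaction_free <- function(sim) {
  log <- sim$event_log[sim$event_log$applied, ]
  fis <- log[log$kind == "fission", ]
  units <- if (nrow(fis)) vapply(fis$participants, `[[`, "", 1) else character()
  for (u in unique(units)) {
    clades <- lapply(fis$node[units == u], function(nd) {
      karyotree:::tips_below(sim$tree, nd)
    })
    clades <- clades[order(-vapply(clades, length, 1L))]
    for (i in seq_along(clades)[-1]) {
      if (!all(clades[[i]] %in% clades[[i - 1]])) return(FALSE)
    }
  }
  fus <- log[log$kind == "fusion", ]
  if (nrow(fus) >= 2) {
    cl <- lapply(fus$node, function(nd) sort(karyotree:::tips_below(sim$tree, nd)))
    for (i in seq_len(nrow(fus) - 1)) {
      for (j in (i + 1):nrow(fus)) {
        if (length(intersect(fus$participants[[i]], fus$participants[[j]])) > 0 &&
          identical(cl[[i]], cl[[j]])) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# Sorted multiset of column signatures of a char_matrix (rows aligned by
# sorted taxon name), for column-for-column comparisons up to order.
column_signatures <- function(m) {
  st <- m$states[order(rownames(m$states)), , drop = FALSE]
  unname(sort(apply(st, 2, paste, collapse = "")))
}

# The packaged 8-taxon reconstructed study maps.
study_maps <- function() {
  all5 <- parse_homology_tsv(karyotree_example("table5_all_species.tsv"))
  tru <- parse_homology_tsv(karyotree_example("turdus_synthetic.tsv"))
  taxa8 <- c("AHY", "ACH", "PFR", "AMA", "MMO", "AAE", "GGA", "TRU")
  maps <- dplyr::bind_rows(all5, tru)
  karyotree:::new_homology_map(maps[maps$taxon %in% taxa8, , drop = FALSE])
}
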