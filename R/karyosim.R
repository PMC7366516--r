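# Karyotype evolution simulator.
#
# A genome is a list of chromosomes; a chromosome is an ordered run of
# segments, each remembering which ancestral chromosome it came from
# (PAK1..PAK15 or MIC1..MICk), its segment index within that ancestral
# chromosome and its orientation. Template chromosomes are pre-segmented
# (macros into 6 segments, micros into 2 by default) so fission has
# boundaries to cut from the outset. Three move types act along each
# branch of a known tree, with Poisson(rate x branch length) counts:
#
#   fusion    - concatenates two chromosomes end to end (tandem);
#   fission   - cuts one chromosome at a segment boundary;
#   inversion - flips a contiguous run of segments in place (changes
#               internal order only, hence invisible to whole-chromosome
#               homology maps - mirroring the real data's limitation).
#
# With allow_breakpoint_reuse = FALSE the bookkeeping is global across the
# whole tree: a template boundary may be cut at most once anywhere, fusion
# junctions may never be re-cut, and no pair of ancestral chromosomes may
# fuse twice independently. Under these rules every realised event maps to
# a unique derived character state, so simulated histories are
# homoplasy-free and event detection on the tip maps can be checked
# against the simulator's own event log.

#' Ancestral karyotype template for simulations
#'
#' The default emulates a putative ancestral avian karyotype: 15
#' macrochromosomes (PAK1..PAK15) plus 25 microchromosome pairs, 2n = 80.
#'
#' @param n_macro,n_micro Numbers of macro- and microchromosome pairs.
#' @param macro_segments,micro_segments Segments per template chromosome
#'   (fission can only cut at segment boundaries).
#' @return An `ancestral_template` object.
#' @export
ancestral_template <- function(n_macro = 15, n_micro = 25,
                               macro_segments = 6, micro_segments = 2) {
  labels <- c(
    paste0("PAK", seq_len(n_macro)),
    if (n_micro > 0) paste0("MIC", seq_len(n_micro))
  )
  sizes <- c(rep(macro_segments, n_macro), rep(micro_segments, n_micro))
  chroms <- purrr::map2(labels, sizes, function(lab, k) {
    list(anc = rep(lab, k), seg = seq_len(k), ori = rep(1L, k))
  })
  structure(
    list(chromosomes = chroms, labels = labels, diploid_number = 2L * length(labels)),
    class = "ancestral_template"
  )
}

#' Rates for the karyotype evolution model
#'
#' Expected events per unit branch length. Defaults (fusion 0.5, fission
#' 0.5, inversion 0.25) give matrices of roughly the size seen in
#' comparative painting studies on trees of total length a few tens of
#' units.
#'
#' @param fusion_rate,fission_rate,inversion_rate Non-negative rates.
#' @param allow_breakpoint_reuse If `FALSE` (default), breakpoints are
#'   single-use globally; see the package vignette.
#' @return An `evolution_model` object.
#' @export
evolution_model <- function(fusion_rate = 0.5, fission_rate = 0.5,
                            inversion_rate = 0.25,
                            allow_breakpoint_reuse = FALSE) {
  rates <- c(fusion_rate, fission_rate, inversion_rate)
  if (any(rates < 0)) abort("rates must be non-negative")
  if (all(rates == 0)) {
    warn("all rates are zero: the simulation is degenerate (no events)")
  }
  structure(
    list(
      fusion_rate = fusion_rate, fission_rate = fission_rate,
      inversion_rate = inversion_rate,
      allow_breakpoint_reuse = allow_breakpoint_reuse
    ),
    class = "evolution_model"
  )
}

# ---- elementary moves (shared by simulate and replay) ----------------------

apply_fusion <- function(state, i, j) {
  state[[i]] <- list(
    anc = c(state[[i]]$anc, state[[j]]$anc),
    seg = c(state[[i]]$seg, state[[j]]$seg),
    ori = c(state[[i]]$ori, state[[j]]$ori)
  )
  state[j] <- NULL
  state
}

apply_fission <- function(state, i, r) {
  ch <- state[[i]]
  left <- list(anc = ch$anc[1:r], seg = ch$seg[1:r], ori = ch$ori[1:r])
  k <- length(ch$anc)
  right <- list(
    anc = ch$anc[(r + 1):k], seg = ch$seg[(r + 1):k], ori = ch$ori[(r + 1):k]
  )
  state[[i]] <- left
  state[[length(state) + 1]] <- right
  state
}

apply_inversion <- function(state, i, a, b) {
  ch <- state[[i]]
  idx <- seq_along(ch$anc)
  idx[a:b] <- rev(idx[a:b])
  state[[i]] <- list(
    anc = ch$anc[idx], seg = ch$seg[idx],
    ori = ifelse(seq_along(idx) %in% a:b, -ch$ori[idx], ch$ori[idx])
  )
  state
}

apply_event <- function(state, kind, params) {
  switch(kind,
    fusion = apply_fusion(state, params$i, params$j),
    fission = apply_fission(state, params$i, params$r),
    inversion = apply_inversion(state, params$i, params$a, params$b)
  )
}

# Original template boundaries of a chromosome: positions r such that the
# segments r, r+1 are adjacent pieces of the same ancestral chromosome in
# consistent orientation. Returned with their global identity keys.
original_boundaries <- function(ch) {
  k <- length(ch$anc)
  if (k < 2) {
    return(tibble::tibble(r = integer(), key = character()))
  }
  r <- seq_len(k - 1)
  same <- ch$anc[r] == ch$anc[r + 1] & ch$ori[r] == ch$ori[r + 1] &
    ((ch$ori[r] == 1L & ch$seg[r + 1] == ch$seg[r] + 1L) |
      (ch$ori[r] == -1L & ch$seg[r + 1] == ch$seg[r] - 1L))
  r <- r[same]
  tibble::tibble(
    r = r,
    key = paste0(ch$anc[r], ":", pmin(ch$seg[r], ch$seg[r + 1]))
  )
}

# ---- proposal machinery ----------------------------------------------------

propose_fusion <- function(state, reg, reuse, max_tries = 100) {
  if (length(state) < 2) return(NULL)
  for (t in seq_len(max_tries)) {
    ij <- sample.int(length(state), 2)
    la <- unique(state[[ij[1]]]$anc)
    lb <- unique(state[[ij[2]]]$anc)
    if (!reuse) {
      pairs <- as.vector(outer(la, lb, function(x, y) {
        paste(pmin(x, y), pmax(x, y), sep = "|")
      }))
      if (any(pairs %in% reg$fused_pairs)) next
    }
    return(list(i = ij[1], j = ij[2]))
  }
  NULL
}

propose_fission <- function(state, reg, reuse, max_tries = 100) {
  multi <- which(vapply(state, function(ch) length(ch$anc) >= 2, TRUE))
  if (length(multi) == 0) return(NULL)
  for (t in seq_len(max_tries)) {
    i <- multi[sample.int(length(multi), 1)]
    if (reuse) {
      r <- sample.int(length(state[[i]]$anc) - 1, 1)
      return(list(i = i, r = r, key = NA_character_))
    }
    bnd <- original_boundaries(state[[i]])
    bnd <- bnd[!(bnd$key %in% reg$used_boundaries), , drop = FALSE]
    if (nrow(bnd) == 0) next # resample another chromosome
    pick <- sample.int(nrow(bnd), 1)
    return(list(i = i, r = bnd$r[pick], key = bnd$key[pick]))
  }
  NULL
}

propose_inversion <- function(state) {
  multi <- which(vapply(state, function(ch) length(ch$anc) >= 2, TRUE))
  if (length(multi) == 0) return(NULL)
  i <- multi[sample.int(length(multi), 1)]
  k <- length(state[[i]]$anc)
  a <- sample.int(k - 1, 1)
  b <- a + sample.int(k - a, 1)
  list(i = i, a = a, b = b)
}

# ---- tree helpers ----------------------------------------------------------

tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

#' Fixed 8-taxon study tree for simulation experiments
#'
#' A balanced rooted binary tree over taxa A..H with internal branches of
#' length 5 and pendant branches of length 2 - long enough internal edges
#' that, at the default rates, each expects about five coded
#' rearrangements.
#'
#' @return A rooted `phylo` with branch lengths.
#' @export
sim_study_tree <- function() {
  ape::read.tree(
    text = "(((A:2,B:2):5,(C:2,D:2):5):5,((E:2,F:2):5,(G:2,H:2):5):5);"
  )
}

# ---- the simulator ---------------------------------------------------------

#' Simulate karyotype evolution along a known tree
#'
#' Fusion, fission and inversion events accumulate along each branch with
#' Poisson(rate x branch length) counts, starting from the ancestral
#' template at the root. Tip karyotypes are expressed as homology maps
#' against the template labels, exactly as chromosome painting would
#' report them (whole-chromosome membership; inversions invisible).
#'
#' @param tree Rooted binary `phylo` with positive branch lengths.
#' @param model An [evolution_model()].
#' @param template An [ancestral_template()].
#' @param seed Integer seed; the run is fully reproducible.
#' @return A `karyosim` object with fields `maps` (homology map tibble for
#'   all tips), `tree`, `event_log`, `tip_states`, `template`, `model`,
#'   `seed`.
#' @export
#' @examples
#' sim <- simulate_karyotypes(sim_study_tree(), seed = 1)
#' dplyr::count(sim$event_log, kind)
simulate_karyotypes <- function(tree, model = evolution_model(),
                                template = ancestral_template(), seed = 1L) {
  if (is.null(tree$edge.length)) {
    abort("simulate_karyotypes() needs a tree with branch lengths")
  }
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    abort("simulate_karyotypes() needs a rooted binary tree")
  }
  if (any(tree$edge.length <= 0)) abort("branch lengths must be positive")
  n <- length(tree$tip.label)
  reg <- new.env(parent = emptyenv())
  reg$fused_pairs <- character(0)
  reg$used_boundaries <- character(0)
  reuse <- model$allow_breakpoint_reuse
  log_rows <- list()
  states <- vector("list", n + tree$Nnode)
  root <- n + 1L
  states[[root]] <- template$chromosomes
  eid <- 0L
  with_seed(seed, {
    tr_pre <- stats::reorder(tree, "cladewise")
    edges_pre <- tr_pre$edge
    lens <- tr_pre$edge.length
    for (e in seq_len(nrow(edges_pre))) {
      parent <- edges_pre[e, 1]
      child <- edges_pre[e, 2]
      len <- lens[e]
      state <- states[[parent]]
      counts <- c(
        fusion = rpois(1, model$fusion_rate * len),
        fission = rpois(1, model$fission_rate * len),
        inversion = rpois(1, model$inversion_rate * len)
      )
      kinds <- rep(names(counts), counts)
      if (length(kinds) > 1) kinds <- sample(kinds)
      ord <- 0L
      for (kind in kinds) {
        params <- switch(kind,
          fusion = propose_fusion(state, reg, reuse),
          fission = propose_fission(state, reg, reuse),
          inversion = propose_inversion(state)
        )
        eid <- eid + 1L
        ord <- ord + 1L
        if (is.null(params)) {
          log_rows[[length(log_rows) + 1]] <- tibble::tibble(
            event_id = eid, node = child, order = ord, kind = kind,
            applied = FALSE, participants = list(character()),
            params = list(NULL)
          )
          next
        }
        participants <- switch(kind,
          fusion = sort(unique(c(
            state[[params$i]]$anc, state[[params$j]]$anc
          ))),
          fission = state[[params$i]]$anc[params$r],
          inversion = sort(unique(state[[params$i]]$anc[params$a:params$b]))
        )
        if (kind == "fusion" && !reuse) {
          la <- unique(state[[params$i]]$anc)
          lb <- unique(state[[params$j]]$anc)
          reg$fused_pairs <- c(reg$fused_pairs, as.vector(
            outer(la, lb, function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|"))
          ))
        }
        if (kind == "fission" && !reuse) {
          reg$used_boundaries <- c(reg$used_boundaries, params$key)
        }
        state <- apply_event(state, kind, params)
        log_rows[[length(log_rows) + 1]] <- tibble::tibble(
          event_id = eid, node = child, order = ord, kind = kind,
          applied = TRUE, participants = list(participants),
          params = list(params)
        )
      }
      states[[child]] <- state
    }
  })
  event_log <- if (length(log_rows) > 0) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(
      event_id = integer(), node = integer(), order = integer(),
      kind = character(), applied = logical(), participants = list(),
      params = list()
    )
  }
  tip_states <- setNames(states[seq_len(n)], tree$tip.label)
  maps <- dplyr::bind_rows(purrr::imap(tip_states, state_to_map))
  structure(
    list(
      maps = new_homology_map(maps), tree = tree, event_log = event_log,
      tip_states = tip_states, template = template, model = model, seed = seed
    ),
    class = "karyosim"
  )
}

# Express a genome state as a homology map for one taxon. Chromosomes are
# numbered deterministically: by decreasing segment count, then by their
# ancestral content.
state_to_map <- function(state, taxon) {
  sizes <- vapply(state, function(ch) length(ch$anc), 1L)
  content <- vapply(state, function(ch) paste(sort(unique(ch$anc)), collapse = "+"), "")
  ord <- order(-sizes, content)
  rows <- purrr::imap(state[ord], function(ch, pos) {
    tibble::tibble(
      taxon = taxon,
      ancestral_chr = unique(ch$anc),
      ancestral_region = "whole",
      descendant_chr = paste0("C", pos),
      descendant_region = "whole",
      evidence = "inferred",
      diploid_number = 2L * length(state)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.karyosim <- function(x, ...) {
  cat(
    "<karyosim> ", length(x$tip_states), " tips, ",
    sum(x$event_log$applied), " events (seed ", x$seed, ")\n",
    sep = ""
  )
  print(dplyr::count(x$event_log[x$event_log$applied, ], .data$kind))
  invisible(x)
}

#' Event log of a simulation, one row per event
#'
#' @param x A `karyosim`.
#' @param ... Unused.
#' @return The event-log tibble (with list columns `participants`,
#'   `params`).
#' @export
tidy.karyosim <- function(x, ...) x$event_log

#' Replay a simulation's event log from the template
#'
#' Re-applies the logged events branch by branch, independently of the
#' states stored during simulation. Replayed tip karyotypes must equal the
#' simulated ones exactly: the log is a complete record of the history.
#'
#' @param sim A `karyosim`.
#' @return Named list of tip genome states.
#' @export
replay_events <- function(sim) {
  tree <- sim$tree
  n <- length(tree$tip.label)
  states <- vector("list", n + tree$Nnode)
  states[[n + 1L]] <- sim$template$chromosomes
  edges_pre <- stats::reorder(tree, "cladewise")$edge
  log <- sim$event_log[sim$event_log$applied, , drop = FALSE]
  for (e in seq_len(nrow(edges_pre))) {
    parent <- edges_pre[e, 1]
    child <- edges_pre[e, 2]
    state <- states[[parent]]
    branch <- log[log$node == child, , drop = FALSE]
    branch <- branch[order(branch$order), , drop = FALSE]
    for (i in seq_len(nrow(branch))) {
      state <- apply_event(state, branch$kind[i], branch$params[[i]])
    }
    states[[child]] <- state
  }
  setNames(states[seq_len(n)], tree$tip.label)
}

#' True character matrix implied by a simulation's event log
#'
#' One binary column per applied fusion or fission event (inversions are
#' invisible to homology maps and are skipped): a tip scores 1 exactly
#' when the event lies on its root-to-tip path, i.e. the 1-taxa of each
#' column form the clade subtended by the event's branch. With breakpoint
#' reuse disabled no event is ever undone, so these columns are
#' homoplasy-free on the true tree by construction.
#'
#' @param result A `karyosim`.
#' @return A `char_matrix` over the simulated tips.
#' @export
truth_matrix <- function(result) {
  tree <- result$tree
  taxa <- tree$tip.label
  log <- result$event_log
  log <- log[log$applied & log$kind %in% c("fusion", "fission"), , drop = FALSE]
  if (nrow(log) == 0) {
    st <- matrix(integer(0), nrow = length(taxa), ncol = 0,
      dimnames = list(taxa, NULL))
    return(char_matrix(st))
  }
  ids <- sprintf("E%03d.%s", log$event_id, log$kind)
  st <- matrix(0L, length(taxa), nrow(log), dimnames = list(taxa, ids))
  for (j in seq_len(nrow(log))) {
    st[tips_below(tree, log$node[j]), j] <- 1L
  }
  chars <- tibble::tibble(
    id = ids,
    kind = ifelse(log$kind == "fusion", "fusion-association", "fission-pattern"),
    label = vapply(log$participants, function(p) paste(p, collapse = "/"), ""),
    units = log$participants,
    min_count = rep(NA_integer_, nrow(log))
  )
  char_matrix(st, chars)
}
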