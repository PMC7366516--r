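# Tree machinery shared by the parsimony engine.
#
# Unrooted binary trees are ape "phylo" objects at the interface. For the
# Fitch kernel they are converted to a compact postorder encoding (see
# src/fitch.cpp): leaves are numbered by their position in a fixed taxon
# vector, the tree is rooted at the pendant edge of leaf 1 and each
# internal vertex lists its two children in postorder.

# ---- encoding <-> phylo ----------------------------------------------------

# Edge-list representation: integer matrix, leaves 1..n, internals
# n+1..2n-2. Used by stepwise addition and TBR.
phylo_to_edgelist <- function(phy, taxa) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  if (!setequal(phy$tip.label, taxa)) {
    abort("tree leaf set does not match the requested taxa")
  }
  tipmap <- match(phy$tip.label, taxa)
  # ape numbers tips 1..n and internals n+1..; remap tips to taxon indices
  e <- phy$edge
  remap <- function(v) ifelse(v <= n, tipmap[v], v)
  cbind(remap(e[, 1]), remap(e[, 2]))
}

# Postorder encoding from an edge list over leaf ids `leaves` (sorted
# subset of 1..n). Leaves are relabelled 1..k in the order of `leaves`;
# the tree is rooted at the pendant edge of the first leaf.
edgelist_encode <- function(edges, leaves) {
  k <- length(leaves)
  ids <- sort(unique(as.vector(edges)))
  internal <- setdiff(ids, leaves)
  nid <- max(ids)
  relab <- integer(nid)
  relab[leaves] <- seq_len(k)
  # adjacency
  deg <- tabulate(as.vector(edges), nid)
  adj <- vector("list", nid)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  if (k == 2) return(integer(0))
  root <- adj[[leaves[1]]][1]
  # iterative DFS to postorder internals
  stack <- root
  parent <- integer(nid)
  parent[root] <- leaves[1]
  outstack <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    outstack <- c(outstack, v)
    for (w in adj[[v]]) {
      if (w != parent[v] && !(w %in% leaves)) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  post <- rev(outstack)
  pos <- integer(nid)
  pos[post] <- seq_along(post)
  enc <- integer(2 * length(post))
  for (i in seq_along(post)) {
    v <- post[i]
    ch <- setdiff(adj[[v]], parent[v])
    vals <- ifelse(ch %in% leaves, relab[ch], k + pos[ch])
    enc[c(2 * i - 1, 2 * i)] <- vals
  }
  enc
}

encode_phylo <- function(phy, taxa) {
  edgelist_encode(phylo_to_edgelist(phy, taxa), seq_along(taxa))
}

# Newick from an encoding; returns an unrooted phylo with a basal
# trichotomy at the vertex adjacent to leaf 1.
decode_tree <- function(enc, taxa) {
  n <- length(taxa)
  nint <- length(enc) / 2
  lab <- function(v) {
    if (v <= n) {
      taxa[v]
    } else {
      p <- v - n
      paste0("(", lab(enc[2 * p - 1]), ",", lab(enc[2 * p]), ")")
    }
  }
  nwk <- paste0(
    "(", taxa[1], ",", lab(enc[2 * nint - 1]), ",", lab(enc[2 * nint]), ");"
  )
  ape::read.tree(text = nwk)
}

# ---- topology enumeration --------------------------------------------------

#' Number of unrooted binary topologies for n taxa
#'
#' The double factorial (2n-5)!!.
#'
#' @param n Number of taxa (>= 3).
#' @return A double (exact for the sizes exhaustive search accepts).
#' @export
n_unrooted_topologies <- function(n) {
  if (n < 3) abort("need at least 3 taxa")
  if (n == 3) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}

# All addition-edge sequences (one per topology).
all_addition_sequences <- function(n) {
  if (n == 3) {
    return(matrix(integer(0), nrow = 1, ncol = 0))
  }
  grid <- expand.grid(lapply(4:n, function(k) seq_len(2 * (k - 1) - 3)))
  as.matrix(grid)
}

# Encodings of every unrooted binary topology on n taxa.
enumerate_topologies <- function(n) {
  seqs <- all_addition_sequences(n)
  storage.mode(seqs) <- "integer"
  build_trees_cpp(n, seqs)
}

# ---- bipartitions ----------------------------------------------------------

# Canonical clade key: the taxa of the bipartition side NOT containing the
# anchor (the alphabetically first taxon), sorted and joined by "|".
clade_key <- function(taxa_in_clade) {
  paste(sort(taxa_in_clade), collapse = "|")
}

# Keys of the non-trivial bipartitions of a phylo (binary or multifurcating,
# rooted trees are treated as unrooted).
tree_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  if (n < 4) return(character(0))
  anchor <- sort(phy$tip.label)[1]
  phy2 <- stats::reorder(phy, "postorder")
  nnode <- n + phy2$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(n)) sets[[i]] <- phy2$tip.label[i]
  for (i in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[i, 1]
    c <- phy2$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  keys <- character(0)
  for (i in seq_len(nrow(phy2$edge))) {
    c <- phy2$edge[i, 2]
    if (c <= n) next
    side <- sets[[c]]
    if (anchor %in% side) side <- setdiff(phy2$tip.label, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, clade_key(side))
    }
  }
  unique(keys)
}

# Bipartition keys straight from an encoding (fast path; n <= 52).
encoding_bipartitions <- function(enc, taxa) {
  n <- length(taxa)
  if (n < 4) return(character(0))
  masks <- subtree_masks_cpp(enc, n)
  masks <- masks[-length(masks)] # root mask = all but leaf 1: trivial
  anchor <- sort(taxa)[1]
  bits <- 2^(seq_len(n) - 1)
  in_mask <- if (n <= 30) {
    function(m) bitwAnd(as.integer(m), as.integer(bits)) > 0
  } else {
    function(m) bitwAnd_double(m, n)
  }
  keys <- vapply(masks, function(m) {
    members <- taxa[in_mask(m)]
    if (length(members) < 2 || length(members) > n - 2) return(NA_character_)
    if (anchor %in% members) members <- setdiff(taxa, members)
    clade_key(members)
  }, "")
  unique(keys[!is.na(keys)])
}

# which leaves are set in a double bitmask
bitwAnd_double <- function(mask, n) {
  out <- logical(n)
  for (i in n:1) {
    p <- 2^(i - 1)
    if (mask >= p) {
      out[i] <- TRUE
      mask <- mask - p
    }
  }
  out
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two trees' non-trivial
#' bipartition sets. Zero means identical unrooted topologies.
#'
#' @param a,b Trees (`phylo`) over the same leaf set.
#' @return A non-negative integer.
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    abort("robinson_foulds() needs two trees on the same leaf set")
  }
  ba <- tree_bipartitions(a)
  bb <- tree_bipartitions(b)
  length(setdiff(ba, bb)) + length(setdiff(bb, ba))
}

# ---- consensus -------------------------------------------------------------

# Build a (possibly multifurcating) phylo from a set of mutually compatible
# clades given as character vectors of taxon names not containing `anchor`.
# Optional `labels` (same length as clades) become node labels.
tree_from_clades <- function(clades, taxa, labels = NULL) {
  anchor <- sort(taxa)[1]
  rest <- setdiff(taxa, anchor)
  keyed <- vapply(clades, clade_key, "")
  lab_of <- function(members) {
    if (is.null(labels)) return("")
    i <- match(clade_key(members), keyed)
    if (is.na(i)) "" else as.character(labels[i])
  }
  build <- function(tipset, avail) {
    inside <- avail[vapply(avail, function(cl) all(cl %in% tipset), TRUE)]
    sizes <- vapply(inside, length, 1L)
    ord <- order(-sizes)
    inside <- inside[ord]
    used <- character(0)
    parts <- character(0)
    for (cl in inside) {
      if (any(cl %in% used)) next # nested clades are handled recursively
      sub <- inside[vapply(inside, function(x) {
        length(x) < length(cl) && all(x %in% cl)
      }, TRUE)]
      parts <- c(parts, paste0(
        "(", paste(build_inner(cl, sub), collapse = ","), ")", lab_of(cl)
      ))
      used <- c(used, cl)
    }
    singles <- setdiff(tipset, used)
    c(parts, singles)
  }
  build_inner <- function(tipset, avail) build(tipset, avail)
  items <- build(rest, clades)
  nwk <- paste0("(", anchor, ",", paste(items, collapse = ","), ");")
  phy <- ape::read.tree(text = nwk)
  phy
}

check_same_leaves <- function(trees) {
  taxa <- trees[[1]]$tip.label
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) {
      abort("all trees must share the same leaf set")
    }
  }
  sort(taxa)
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the clades present in every input tree; conflicting
#' regions collapse to polytomies.
#'
#' @param trees A list or `multiPhylo` of trees on the same leaf set.
#' @return A `phylo` (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0) abort("strict_consensus() needs at least one tree")
  taxa <- check_same_leaves(trees)
  if (length(trees) == 1) return(trees[[1]])
  keys <- lapply(trees, tree_bipartitions)
  shared <- Reduce(intersect, keys)
  clades <- lapply(shared, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  tree_from_clades(clades, taxa)
}

#' Majority-rule consensus of a set of trees
#'
#' Retains the clades present in more than `threshold` of the trees
#' (`threshold = 0.5` is the usual majority rule; clades above one half are
#' always mutually compatible).
#'
#' @param trees A list or `multiPhylo` of trees on the same leaf set.
#' @param threshold Fraction in `[0.5, 1)`.
#' @return A `phylo` with node labels giving each clade's percentage.
#' @export
majority_rule <- function(trees, threshold = 0.5) {
  trees <- unclass(trees)
  if (length(trees) == 0) abort("majority_rule() needs at least one tree")
  if (threshold < 0.5 || threshold >= 1) {
    abort("threshold must be in [0.5, 1) so retained clades are compatible")
  }
  taxa <- check_same_leaves(trees)
  keys <- unlist(lapply(trees, tree_bipartitions))
  tab <- table(keys)
  keep <- names(tab)[tab > threshold * length(trees)]
  pct <- round(100 * as.integer(tab[keep]) / length(trees))
  clades <- lapply(keep, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  tree_from_clades(clades, taxa, labels = pct)
}

# ---- rooting ---------------------------------------------------------------

#' Root a tree on an outgroup
#'
#' Roots on the edge separating the outgroup from the ingroup when the
#' outgroup is a clade of the unrooted tree. Otherwise the root is placed
#' on the edge whose bipartition best matches the outgroup (fewest taxa on
#' the wrong side), with a warning.
#'
#' @param tree A `phylo`.
#' @param outgroup Character vector of outgroup taxon names (a proper,
#'   non-empty subset of the leaves).
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  taxa <- tree$tip.label
  if (length(outgroup) == 0 || !all(outgroup %in% taxa)) {
    abort("outgroup must be a non-empty subset of the tree's leaves")
  }
  if (setequal(outgroup, taxa)) {
    abort("outgroup cannot be the entire leaf set")
  }
  if (length(outgroup) == 1) {
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  keys <- tree_bipartitions(tree)
  og_key_sides <- c(clade_key(outgroup), clade_key(setdiff(taxa, outgroup)))
  if (any(og_key_sides %in% keys)) {
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  # best split: minimise taxa on the wrong side of the candidate edge
  sides <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  sides <- c(sides, lapply(sides, function(s) setdiff(taxa, s)),
    as.list(taxa))
  mismatch <- vapply(sides, function(s) {
    length(setdiff(outgroup, s)) + length(setdiff(s, outgroup))
  }, 1L)
  best <- sides[[which.min(mismatch)]]
  warn(paste0(
    "outgroup {", paste(outgroup, collapse = ", "),
    "} is not monophyletic on this tree; rooting on the closest edge"
  ))
  ape::root(tree, outgroup = best, resolve.root = TRUE)
}

# ---- random topologies (tests, simulator) ----------------------------------

# A uniform random unrooted binary topology over `taxa` (uses the current
# RNG stream).
random_topology <- function(taxa) {
  n <- length(taxa)
  if (n == 3) {
    seqs <- matrix(integer(0), 1, 0)
  } else {
    seqs <- matrix(
      vapply(4:n, function(k) sample.int(2 * (k - 1) - 3, 1), 1L),
      nrow = 1
    )
  }
  enc <- build_trees_cpp(n, seqs)
  decode_tree(enc[1, ], taxa)
}
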