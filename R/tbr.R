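# Tree bisection and reconnection (TBR).
#
# Every edge of the unrooted tree is bisected; the two resulting fragments
# (with their degree-2 stumps suppressed) are reconnected by joining every
# edge of one to every edge of the other. The union over all bisections,
# minus the input topology, is the TBR neighborhood. For a pendant edge
# the detached leaf reattaches to every edge of the other fragment, so SPR
# (and NNI) moves are a subset.

# Core: edge-list in, list of edge-lists out (deduplicated topologies).
tbr_neighbor_edgelists <- function(edges, n) {
  m <- nrow(edges)
  nid <- max(edges)
  adj <- vector("list", nid)
  for (i in seq_len(m)) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  taxa_idx <- seq_len(n)
  orig_key <- paste(sort(encoding_bipartitions(
    edgelist_encode(edges, taxa_idx), as.character(taxa_idx)
  )), collapse = ";")
  seen <- new.env(parent = emptyenv())
  assign(orig_key, TRUE, envir = seen)
  out <- list()

  component <- function(start, block_u, block_v) {
    comp <- integer(0)
    stack <- start
    visited <- logical(nid)
    visited[start] <- TRUE
    while (length(stack) > 0) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, x)
      for (w in adj[[x]]) {
        if ((x == block_u && w == block_v) || (x == block_v && w == block_u)) next
        if (!visited[w]) {
          visited[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    comp
  }

  for (e in seq_len(m)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    compA <- component(u, u, v)
    compB <- setdiff(seq_len(nid)[tabulate(as.vector(edges), nid) > 0], compA)
    frag <- function(comp, stub) {
      rows <- edges[edges[, 1] %in% comp & edges[, 2] %in% comp, , drop = FALSE]
      if (length(comp) == 1) {
        return(list(edges = rows[0, , drop = FALSE], single = stub))
      }
      nb <- intersect(adj[[stub]], comp)
      # suppress the degree-2 stub
      keep <- !(rows[, 1] == stub | rows[, 2] == stub)
      rows2 <- rows[keep, , drop = FALSE]
      rows2 <- rbind(rows2, nb)
      list(edges = rows2, single = NA_integer_)
    }
    A <- frag(compA, u)
    B <- frag(compB, v)
    attachA <- if (!is.na(A$single)) list(NULL) else {
      lapply(seq_len(nrow(A$edges)), function(i) A$edges[i, ])
    }
    attachB <- if (!is.na(B$single)) list(NULL) else {
      lapply(seq_len(nrow(B$edges)), function(i) B$edges[i, ])
    }
    for (a in attachA) {
      for (b in attachB) {
        if (is.null(a)) {
          eA <- matrix(integer(0), 0, 2)
          pa <- A$single
        } else {
          keep <- !(A$edges[, 1] == a[1] & A$edges[, 2] == a[2])
          eA <- rbind(A$edges[keep, , drop = FALSE], c(a[1], u), c(u, a[2]))
          pa <- u
        }
        if (is.null(b)) {
          eB <- matrix(integer(0), 0, 2)
          pb <- B$single
        } else {
          keep <- !(B$edges[, 1] == b[1] & B$edges[, 2] == b[2])
          eB <- rbind(B$edges[keep, , drop = FALSE], c(b[1], v), c(v, b[2]))
          pb <- v
        }
        newe <- rbind(eA, eB, c(pa, pb))
        enc <- edgelist_encode(newe, taxa_idx)
        key <- paste(sort(encoding_bipartitions(enc, as.character(taxa_idx))),
          collapse = ";")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1]] <- newe
        }
      }
    }
  }
  out
}

#' TBR neighborhood of an unrooted tree
#'
#' All distinct topologies reachable from `tree` by one tree bisection and
#' reconnection move. The input topology itself is excluded.
#'
#' @param tree An unrooted binary `phylo` with at least 4 leaves.
#' @return A `multiPhylo` of neighbor topologies.
#' @export
#' @examples
#' quartet <- ape::read.tree(text = "((A,B),(C,D));")
#' length(tbr_neighbors(quartet)) # the 2 alternative quartet topologies
tbr_neighbors <- function(tree) {
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  if (n < 4) abort("tbr_neighbors() needs at least 4 leaves")
  edges <- phylo_to_edgelist(tree, taxa)
  els <- tbr_neighbor_edgelists(edges, n)
  out <- lapply(els, function(e) decode_tree(edgelist_encode(e, seq_len(n)), taxa))
  class(out) <- "multiPhylo"
  out
}
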