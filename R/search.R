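# Maximum parsimony tree search: exhaustive enumeration and
# random-addition-sequence stepwise addition followed by TBR hill climbing
# with a pool of equally parsimonious trees (PAUP-style MULTREES).

new_search_result <- function(mp_encodings, taxa, length, matrix, log) {
  trees <- lapply(mp_encodings, decode_tree, taxa = taxa)
  class(trees) <- "multiPhylo"
  per_char <- tibble::tibble(
    id = colnames(matrix$states),
    min_steps = min_steps(matrix),
    observed_steps = as.integer(fitch_steps(mp_encodings[[1]], matrix)),
    max_steps = max_steps(matrix)
  )
  stats <- compute_fit_statistics(length, matrix)
  structure(
    list(
      mp_trees = trees,
      length = as.integer(length),
      ci = stats$ci, hi = stats$hi, ri = stats$ri,
      per_character = per_char,
      taxa = taxa,
      search_log = log
    ),
    class = "parsimony_search"
  )
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("<parsimony_search> (", x$search_log$method, ")\n", sep = "")
  cat(
    "  ", length(x$mp_trees), " most parsimonious tree(s), length ", x$length,
    "\n  CI = ", format(round(x$ci, 4)), ", HI = ", format(round(x$hi, 4)),
    ", RI = ", ifelse(is.na(x$ri), "undefined", format(round(x$ri, 4))), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-character fit of a parsimony search
#'
#' @param x A `parsimony_search`.
#' @param ... Unused.
#' @return A tibble with per-character minimum, observed and maximum steps
#'   and the per-character consistency `min_steps / observed_steps`.
#' @export
tidy.parsimony_search <- function(x, ...) {
  dplyr::mutate(
    x$per_character,
    consistency = ifelse(.data$observed_steps == 0, NA_real_,
      .data$min_steps / .data$observed_steps)
  )
}

#' One-row summary of a parsimony search
#'
#' @param x A `parsimony_search`.
#' @param ... Unused.
#' @return A tibble with the tree count, length and ensemble indices.
#' @export
glance.parsimony_search <- function(x, ...) {
  tibble::tibble(
    n_mp_trees = length(x$mp_trees),
    length = x$length,
    ci = x$ci, hi = x$hi, ri = x$ri,
    n_taxa = length(x$taxa),
    n_characters = nrow(x$per_character),
    method = x$search_log$method
  )
}

dedup_encodings <- function(encs, taxa) {
  keys <- vapply(encs, function(e) {
    paste(sort(encoding_bipartitions(e, taxa)), collapse = ";")
  }, "")
  encs[!duplicated(keys)]
}

#' Exhaustive maximum parsimony search
#'
#' Evaluates every unrooted binary topology ((2n-5)!! trees) and returns
#' all trees attaining the minimal Fitch length. Exact and deterministic;
#' refuses more than `max_taxa` taxa, for which [heuristic_search()] is the
#' tool.
#'
#' @param matrix A `char_matrix` with 3 or more taxa.
#' @param max_taxa Refusal threshold (default 10, i.e. about 2 million
#'   topologies).
#' @return A `parsimony_search` object.
#' @export
exhaustive_search <- function(matrix, max_taxa = 10) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 3) abort("exhaustive_search() needs at least 3 taxa")
  if (n > max_taxa) {
    abort(paste0(
      "matrix has ", n, " taxa (> max_taxa = ", max_taxa,
      "); use heuristic_search() for larger problems"
    ))
  }
  trees <- enumerate_topologies(n)
  masks <- state_masks(matrix)
  lens <- fitch_lengths_cpp(trees, masks, rep(1L, ncol(masks)))
  best <- min(lens)
  idx <- which(lens == best)
  encs <- lapply(idx, function(i) trees[i, ])
  new_search_result(
    encs, taxa, best, matrix,
    log = list(
      method = "exhaustive", seed = NA_integer_, replicates = NA_integer_,
      n_topologies = nrow(trees)
    )
  )
}

# Stepwise addition under a given taxon order; returns the full-tree
# edge list. Ties between insertion edges break toward the earliest
# created edge (deterministic given the order).
stepwise_addition <- function(order_idx, masks, n) {
  sub <- sort(order_idx[1:3])
  root_id <- n + 1L
  edges <- rbind(
    c(sub[1], root_id), c(sub[2], root_id), c(sub[3], root_id)
  )
  present <- sub
  next_internal <- n + 2L
  for (k in 4:length(order_idx)) {
    leaf <- order_idx[k]
    best_len <- Inf
    best_edges <- NULL
    cand_encs <- list()
    cand_edges <- list()
    leaves_after <- sort(c(present, leaf))
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      newe <- rbind(
        edges[-e, , drop = FALSE],
        c(u, next_internal), c(next_internal, v), c(next_internal, leaf)
      )
      cand_edges[[length(cand_edges) + 1]] <- newe
      cand_encs[[length(cand_encs) + 1]] <- edgelist_encode(newe, leaves_after)
    }
    enc_mat <- do.call(rbind, cand_encs)
    lens <- fitch_lengths_cpp(
      enc_mat, masks[leaves_after, , drop = FALSE],
      rep(1L, ncol(masks))
    )
    pick <- which.min(lens)
    edges <- cand_edges[[pick]]
    present <- leaves_after
    next_internal <- next_internal + 1L
  }
  edges
}

#' Heuristic maximum parsimony search
#'
#' Random-addition-sequence stepwise addition followed by TBR branch
#' swapping. Each addition replicate hill-climbs, keeping a pool of all
#' equally parsimonious trees and swapping on every pool member until the
#' neighborhood is exhausted; the best trees over all replicates are
#' returned, deduplicated by topology. Fully reproducible for a fixed
#' seed.
#'
#' @param matrix A `char_matrix` with 4 or more taxa.
#' @param n_addition_replicates Number of random addition sequences
#'   (default 10).
#' @param seed Integer seed for the addition sequences.
#' @param max_pool Safety cap on the equally-parsimonious tree pool per
#'   replicate.
#' @return A `parsimony_search` object.
#' @export
heuristic_search <- function(matrix, n_addition_replicates = 10, seed = 1L,
                             max_pool = 2000L) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 4) abort("heuristic_search() needs at least 4 taxa")
  masks <- state_masks(matrix)
  w <- rep(1L, ncol(masks))
  taxa_chr <- as.character(seq_len(n))
  enc_key <- function(enc) {
    paste(sort(encoding_bipartitions(enc, taxa_chr)), collapse = ";")
  }
  best_len <- Inf
  best_pool <- list() # key -> encoding
  n_eval <- 0L
  with_seed(seed, {
    for (rep_i in seq_len(n_addition_replicates)) {
      ord <- sample.int(n)
      edges <- stepwise_addition(ord, masks, n)
      enc <- edgelist_encode(edges, seq_len(n))
      len <- fitch_lengths_cpp(matrix(enc, nrow = 1), masks, w)[1]
      pool <- list(edges)
      pool_keys <- enc_key(enc)
      pool_len <- len
      swapped <- c(FALSE)
      repeat {
        todo <- which(!swapped)
        if (length(todo) == 0) break
        i <- todo[1]
        swapped[i] <- TRUE
        nbs <- tbr_neighbor_edgelists(pool[[i]], n)
        if (length(nbs) == 0) next
        encs <- lapply(nbs, edgelist_encode, leaves = seq_len(n))
        lens <- fitch_lengths_cpp(do.call(rbind, encs), masks, w)
        n_eval <- n_eval + length(lens)
        if (min(lens) < pool_len) {
          keep <- which(lens == min(lens))
          pool <- nbs[keep]
          pool_keys <- vapply(encs[keep], enc_key, "")
          dup <- duplicated(pool_keys)
          pool <- pool[!dup]
          pool_keys <- pool_keys[!dup]
          pool_len <- min(lens)
          swapped <- rep(FALSE, length(pool))
        } else {
          eq <- which(lens == pool_len)
          for (j in eq) {
            k <- enc_key(encs[[j]])
            if (!(k %in% pool_keys) && length(pool) < max_pool) {
              pool[[length(pool) + 1]] <- nbs[[j]]
              pool_keys <- c(pool_keys, k)
              swapped <- c(swapped, FALSE)
            }
          }
        }
      }
      if (pool_len < best_len) {
        best_len <- pool_len
        best_pool <- setNames(
          lapply(pool, edgelist_encode, leaves = seq_len(n)), pool_keys
        )
      } else if (pool_len == best_len) {
        for (j in seq_along(pool)) {
          k <- pool_keys[j]
          if (!(k %in% names(best_pool))) {
            best_pool[[k]] <- edgelist_encode(pool[[j]], seq_len(n))
          }
        }
      }
    }
  })
  new_search_result(
    unname(best_pool), taxa, best_len, matrix,
    log = list(
      method = "heuristic", seed = seed,
      replicates = n_addition_replicates, n_evaluated = n_eval
    )
  )
}
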