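# Fitch parsimony counting and ensemble fit statistics.

# taxa x nchar bitmask matrix: state 0 -> 1, state 1 -> 2, missing -> 3
# (union semantics: a '?' leaf is free to take either state).
state_masks <- function(matrix) {
  st <- matrix$states
  mk <- matrix(3L, nrow(st), ncol(st))
  mk[which(st == 0L)] <- 1L
  mk[which(st == 1L)] <- 2L
  storage.mode(mk) <- "integer"
  mk
}

#' Fitch parsimony length of a tree
#'
#' The minimum total number of unordered state changes the matrix requires
#' on the given topology. Missing states contribute the full state set at
#' the leaf (Fitch union semantics) and the result does not depend on
#' rooting.
#'
#' @param tree A `phylo` whose leaf set equals the matrix taxa.
#' @param matrix A `char_matrix`.
#' @return A non-negative integer.
#' @export
fitch_length <- function(tree, matrix) {
  taxa <- matrix$taxa
  if (!setequal(tree$tip.label, taxa)) {
    abort("tree leaves and matrix taxa differ")
  }
  masks <- state_masks(matrix)
  if (length(taxa) == 2) {
    return(sum(bitwAnd(masks[1, ], masks[2, ]) == 0))
  }
  enc <- encode_phylo(tree, taxa)
  fitch_lengths_cpp(
    matrix(enc, nrow = 1), masks, rep(1L, ncol(masks))
  )[1]
}

# Per-character observed steps on one encoded tree.
fitch_steps <- function(enc, matrix) {
  fitch_steps_cpp(as.integer(enc), state_masks(matrix))
}

# Per-character minimum steps (binary data: 1 if both states observed).
min_steps <- function(matrix) {
  st <- matrix$states
  vapply(seq_len(ncol(st)), function(j) {
    x <- st[, j]
    as.integer(any(x == 0L, na.rm = TRUE) && any(x == 1L, na.rm = TRUE))
  }, 1L)
}

# Per-character maximum steps: parsimony length on the star tree, which
# for a binary character is the minority state count.
max_steps <- function(matrix) {
  st <- matrix$states
  vapply(seq_len(ncol(st)), function(j) {
    x <- st[, j]
    min(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE))
  }, 1L)
}

compute_fit_statistics <- function(length, matrix) {
  m <- sum(min_steps(matrix))
  M <- sum(max_steps(matrix))
  if (length == 0) {
    rlang::inform("tree length is 0; CI defined as 1 by convention")
    ci <- 1
  } else {
    ci <- m / length
  }
  hi <- 1 - ci
  ri <- if (M == m) NA_real_ else (M - length) / (M - m)
  list(ci = ci, hi = hi, ri = ri)
}

#' Ensemble consistency statistics for a search result
#'
#' The ensemble consistency index CI = sum(m) / L (m: minimum conceivable
#' steps per character; L: tree length), homoplasy index HI = 1 - CI, and
#' retention index RI = (sum(M) - L) / (sum(M) - sum(m)) with M the
#' per-character length on the star tree. RI is reported as `NA` when
#' sum(M) = sum(m) (no informative variation). A zero-length tree has
#' CI = 1 by convention.
#'
#' @param result A `parsimony_search` object (or a bare tree length).
#' @param matrix The `char_matrix` the search was run on.
#' @return A list with elements `ci`, `hi`, `ri`.
#' @export
tree_statistics <- function(result, matrix) {
  len <- if (inherits(result, "parsimony_search")) result$length else result
  compute_fit_statistics(len, matrix)
}
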