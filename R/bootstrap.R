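# Nonparametric bootstrap of character matrices with clade support
# summaries. Each replicate resamples characters with replacement to the
# original count, reruns the configured search, and contributes the clades
# of the replicate's strict consensus of MP trees (deterministic given the
# replicate, unlike picking one arbitrary MP tree).

#' Search configuration for bootstrap and pipeline runs
#'
#' @param method `"auto"` (exhaustive up to `max_exhaustive_taxa` taxa,
#'   heuristic beyond), `"exhaustive"` or `"heuristic"`.
#' @param n_addition_replicates Addition sequences per heuristic search.
#' @param max_exhaustive_taxa Taxon cutoff for the auto rule.
#' @return A list of class `search_config`.
#' @export
search_config <- function(method = c("auto", "exhaustive", "heuristic"),
                          n_addition_replicates = 10,
                          max_exhaustive_taxa = 10) {
  method <- match.arg(method)
  structure(
    list(
      method = method,
      n_addition_replicates = n_addition_replicates,
      max_exhaustive_taxa = max_exhaustive_taxa
    ),
    class = "search_config"
  )
}

resolve_method <- function(search, n_taxa) {
  if (search$method != "auto") {
    return(search$method)
  }
  if (n_taxa <= search$max_exhaustive_taxa) "exhaustive" else "heuristic"
}

resample_matrix <- function(matrix, weights) {
  idx <- rep(seq_along(weights), weights)
  st <- matrix$states[, idx, drop = FALSE]
  colnames(st) <- make.unique(colnames(matrix$states)[idx])
  chars <- matrix$characters[idx, , drop = FALSE]
  chars$id <- colnames(st)
  char_matrix(st, chars)
}

#' Nonparametric bootstrap clade support
#'
#' Characters are resampled with replacement to the original count; each
#' replicate is analysed with the configured parsimony search and the
#' clades of its strict consensus of MP trees are recorded. Support for a
#' clade is the percentage of replicates containing it. The whole run is
#' reproducible bit for bit under a fixed seed.
#'
#' @param matrix A `char_matrix`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param search A [search_config()].
#' @return A `parsimony_bootstrap` object: tibble of clade supports, the
#'   majority-rule bootstrap consensus with supports as node labels, the
#'   replicate count and seed. Matrices with no parsimony-informative
#'   character are analysed but flagged (`degenerate = TRUE`).
#' @export
bootstrap <- function(matrix, replicates = 1000, seed = 1L,
                      search = search_config()) {
  if (replicates < 1) abort("bootstrap() needs at least 1 replicate")
  taxa <- matrix$taxa
  n <- length(taxa)
  nchar_ <- ncol(matrix$states)
  if (nchar_ == 0) abort("cannot bootstrap a matrix with no characters")
  method <- resolve_method(search, n)
  degenerate <- !any(classify_characters(matrix)$class == "parsimony-informative")
  if (degenerate) {
    warn("no parsimony-informative characters: bootstrap supports are degenerate")
  }
  counts <- new.env(parent = emptyenv())
  masks <- state_masks(matrix)
  topo <- if (method == "exhaustive") enumerate_topologies(n) else NULL
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      w <- tabulate(sample.int(nchar_, nchar_, replace = TRUE), nchar_)
      if (method == "exhaustive") {
        lens <- fitch_lengths_cpp(topo, masks, as.integer(w))
        idx <- which(lens == min(lens))
        shared <- encoding_bipartitions(topo[idx[1], ], taxa)
        for (i in idx[-1]) {
          if (length(shared) == 0) break
          shared <- intersect(shared, encoding_bipartitions(topo[i, ], taxa))
        }
      } else {
        rs <- heuristic_search(
          resample_matrix(matrix, w),
          n_addition_replicates = search$n_addition_replicates,
          seed = sample.int(.Machine$integer.max, 1)
        )
        shared <- Reduce(intersect, lapply(rs$mp_trees, tree_bipartitions))
      }
      for (k in shared) {
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  })
  keys <- ls(counts)
  supports <- tibble::tibble(
    clade = keys,
    n_replicates = vapply(keys, function(k) counts[[k]], 1L)
  ) |>
    dplyr::mutate(support = 100 * .data$n_replicates / replicates) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$clade)
  maj <- supports[supports$support > 50, , drop = FALSE]
  consensus <- tree_from_clades(
    lapply(maj$clade, function(k) strsplit(k, "|", fixed = TRUE)[[1]]),
    sort(taxa),
    labels = round(maj$support)
  )
  structure(
    list(
      supports = supports,
      consensus = consensus,
      replicates = as.integer(replicates),
      seed = seed,
      method = method,
      degenerate = degenerate
    ),
    class = "parsimony_bootstrap"
  )
}

#' @export
print.parsimony_bootstrap <- function(x, ...) {
  cat(
    "<parsimony_bootstrap> ", x$replicates, " replicates (", x$method,
    " search, seed ", x$seed, ")\n",
    sep = ""
  )
  print(utils::head(x$supports, 10))
  invisible(x)
}

#' Clade supports of a bootstrap run
#'
#' @param x A `parsimony_bootstrap`.
#' @param ... Unused.
#' @return The tibble of clades (taxon names joined by `|`) and supports.
#' @export
tidy.parsimony_bootstrap <- function(x, ...) x$supports

#' One-row summary of a bootstrap run
#'
#' @param x A `parsimony_bootstrap`.
#' @param ... Unused.
#' @return A tibble with replicate count, method and clade counts.
#' @export
glance.parsimony_bootstrap <- function(x, ...) {
  tibble::tibble(
    replicates = x$replicates,
    method = x$method,
    n_clades_seen = nrow(x$supports),
    n_clades_majority = sum(x$supports$support > 50),
    degenerate = x$degenerate
  )
}

#' Bootstrap support for a given taxon set
#'
#' Looks up the support of the clade formed by `taxa` (either side of the
#' bipartition).
#'
#' @param result A `parsimony_bootstrap`.
#' @param taxa Character vector of taxon names.
#' @return Support percentage (0 if the clade was never seen).
#' @export
clade_support <- function(result, taxa) {
  all_taxa <- sort(unique(unlist(strsplit(result$supports$clade, "|", fixed = TRUE))))
  all_taxa <- sort(union(all_taxa, result$consensus$tip.label))
  key1 <- clade_key(taxa)
  key2 <- clade_key(setdiff(all_taxa, taxa))
  hit <- result$supports$support[result$supports$clade %in% c(key1, key2)]
  if (length(hit) == 0) 0 else max(hit)
}
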