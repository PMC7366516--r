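# Binary character coding of chromosome rearrangements.
#
# Characters come in two auto-coded kinds. A *fusion association*
# {PAK8, PAK9} is present in a taxon when some descendant chromosome
# carries painted homology to every participant (possibly among further
# segments: containment semantics, so a later stacked fusion does not erase
# an inherited association). A *fission pattern* (PAK1, k) is present when
# the ancestral chromosome is distributed over at least k descendant
# chromosomes; one character per descendant count observed in the data.
# Coding is done in PAK coordinates, where the two arms of chicken
# chromosome 4 are distinct ancestral chromosomes. Inversions are not
# auto-codable from whole-chromosome homology maps and may be supplied as
# manual `other-discrete` characters.

CHARACTER_KINDS <- c("fusion-association", "fission-pattern", "inversion", "other-discrete")

bind_maps <- function(maps) {
  if (is.data.frame(maps)) {
    df <- tibble::as_tibble(maps)
  } else {
    df <- dplyr::bind_rows(lapply(maps, tibble::as_tibble))
  }
  df
}

# Per (taxon, descendant chromosome) sets of ancestral PAK units,
# unidentified micros dropped.
taxon_chromosome_units <- function(df) {
  conv <- ancestral_to_pak_units(df)
  conv <- conv[conv$unit != "micro", , drop = FALSE]
  conv |>
    dplyr::distinct(.data$taxon, .data$descendant_chr, .data$unit) |>
    dplyr::group_by(.data$taxon, .data$descendant_chr) |>
    dplyr::summarise(units = list(sort(unique(.data$unit))), .groups = "drop")
}

# Per (taxon, unit) descendant chromosome counts.
taxon_unit_counts <- function(df) {
  conv <- ancestral_to_pak_units(df)
  conv <- conv[conv$unit != "micro", , drop = FALSE]
  conv |>
    dplyr::distinct(.data$taxon, .data$unit, .data$descendant_chr) |>
    dplyr::count(.data$taxon, .data$unit, name = "n_descendants")
}

character_id <- function(kind, units, count = NA_integer_) {
  if (kind == "fusion-association") {
    paste0("F.", paste(units, collapse = "+"))
  } else {
    paste0("S.", units, ".ge", count)
  }
}

character_label <- function(kind, units, count = NA_integer_) {
  if (kind == "fusion-association") {
    paste0(paste(units, collapse = "/"), " association")
  } else {
    paste0(units, " fission (>= ", count, " chromosomes)")
  }
}

#' Enumerate rearrangement characters observed across homology maps
#'
#' Builds the deterministic union of (a) every distinct fusion
#' participant set observed in any taxon and (b) every distinct
#' (ancestral chromosome, descendant count >= 2) fission pattern, ordered
#' by kind, then by lowest participating ancestral chromosome number, then
#' by the remaining participants / the count.
#'
#' @param maps A homology map covering two or more taxa (or a list of maps).
#' @param pairwise If `TRUE`, fusion participant sets are decomposed into
#'   all pairs instead of kept whole (sensitivity-analysis mode).
#' @return A tibble with columns `id`, `kind`, `label`, `units`
#'   (list column of ancestral PAK-scheme labels) and `min_count`
#'   (fission patterns only).
#' @export
#' @examples
#' all5 <- parse_homology_tsv(karyotree_example("table5_all_species.tsv"))
#' enumerate_characters(all5)
enumerate_characters <- function(maps, pairwise = FALSE) {
  df <- bind_maps(maps)
  if (length(unique(df$taxon)) < 2) {
    abort("enumerate_characters() needs maps for at least 2 taxa")
  }
  comp <- taxon_chromosome_units(df)
  fus_sets <- comp$units[vapply(comp$units, length, 1L) >= 2]
  if (pairwise) {
    fus_sets <- unlist(
      lapply(fus_sets, function(u) utils::combn(u, 2, simplify = FALSE)),
      recursive = FALSE
    )
  }
  fus_sets <- unique(fus_sets)
  fis <- taxon_unit_counts(df) |>
    dplyr::filter(.data$n_descendants >= 2) |>
    dplyr::distinct(.data$unit, .data$n_descendants)

  fus_tbl <- tibble::tibble(
    kind = rep("fusion-association", length(fus_sets)),
    units = fus_sets,
    min_count = rep(NA_integer_, length(fus_sets))
  )
  fis_tbl <- tibble::tibble(
    kind = rep("fission-pattern", nrow(fis)),
    units = as.list(fis$unit),
    min_count = as.integer(fis$n_descendants)
  )
  out <- dplyr::bind_rows(fus_tbl, fis_tbl)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      id = character(), kind = character(), label = character(),
      units = list(), min_count = integer()
    ))
  }
  key1 <- vapply(out$units, function(u) min(unit_sort_key(u)), 1L)
  key2 <- vapply(out$units, function(u) {
    paste(sprintf("%06d", sort(unit_sort_key(u))), collapse = ".")
  }, "")
  ord <- order(match(out$kind, CHARACTER_KINDS), key1, key2,
    dplyr::coalesce(out$min_count, 0L))
  out <- out[ord, ]
  out$id <- unname(mapply(character_id, out$kind, out$units, out$min_count))
  out$label <- unname(mapply(character_label, out$kind, out$units, out$min_count))
  dplyr::select(out, "id", "kind", "label", "units", "min_count")
}

#' Score one taxon for one rearrangement character
#'
#' Returns `1` when the character's defining rearrangement is observed in
#' the map, `0` when all involved ancestral chromosomes are assigned but
#' the rearrangement is absent, and `?` (reported as `NA`) when any
#' involved ancestral chromosome has no assignment for this taxon.
#'
#' @param map Homology map for a single taxon.
#' @param character One row of [enumerate_characters()] output (or a list
#'   with `kind`, `units`, `min_count`).
#' @param taxon Taxon name, optional for single-taxon maps.
#' @return `1L`, `0L` or `NA_integer_` (missing).
#' @export
score_taxon <- function(map, character, taxon = NULL) {
  m <- single_taxon(bind_maps(map), taxon, "score_taxon()")
  if (is.data.frame(character)) character <- as.list(character[1, ])
  units <- unlist(character$units)
  conv <- ancestral_to_pak_units(m)
  assigned <- unique(conv$unit)
  if (!all(units %in% assigned)) {
    return(NA_integer_)
  }
  if (character$kind == "fusion-association") {
    comp <- taxon_chromosome_units(m)
    hit <- any(vapply(comp$units, function(u) all(units %in% u), TRUE))
    return(as.integer(hit))
  }
  if (character$kind == "fission-pattern") {
    counts <- taxon_unit_counts(m)
    n <- counts$n_descendants[counts$unit == units]
    n <- if (length(n) == 0) 1L else n
    return(as.integer(n >= character$min_count))
  }
  abort(paste0("characters of kind '", character$kind, "' cannot be auto-scored"))
}

#' Build a binary character matrix from homology maps
#'
#' Columns are the characters of [enumerate_characters()] (in their
#' canonical order, so the matrix is invariant to the order maps are
#' supplied in, up to row order); cells are [score_taxon()] states.
#'
#' @inheritParams enumerate_characters
#' @param characters Optional pre-computed character tibble; enumerated
#'   from the maps when `NULL`.
#' @return A `char_matrix` object; see [char_matrix()].
#' @export
#' @examples
#' all5 <- parse_homology_tsv(karyotree_example("table5_all_species.tsv"))
#' m <- build_matrix(dplyr::filter(all5, taxon %in% c("GGA", "AHY", "ACH", "PFR")))
#' m
build_matrix <- function(maps, characters = NULL, pairwise = FALSE) {
  df <- bind_maps(maps)
  taxa <- unique(df$taxon)
  if (length(taxa) < 2) abort("build_matrix() needs at least 2 taxa")
  if (length(taxa) == 2) {
    warn("only 2 taxa: the matrix is valid but no tree topology can be inferred")
  }
  if (is.null(characters)) characters <- enumerate_characters(df, pairwise = pairwise)
  states <- matrix(NA_integer_,
    nrow = length(taxa), ncol = nrow(characters),
    dimnames = list(taxa, characters$id)
  )
  # precompute per-taxon chromosome compositions, unit counts and the set
  # of assigned units, then score every cell from those
  comp <- taxon_chromosome_units(df)
  counts <- taxon_unit_counts(df)
  conv <- ancestral_to_pak_units(df)
  assigned <- split(conv$unit, conv$taxon)
  comp_by_taxon <- split(comp$units, comp$taxon)
  for (t in taxa) {
    t_comp <- comp_by_taxon[[t]] %||% list()
    t_counts <- counts[counts$taxon == t, , drop = FALSE]
    t_assigned <- unique(assigned[[t]] %||% character())
    for (j in seq_len(nrow(characters))) {
      units <- unlist(characters$units[[j]])
      if (!all(units %in% t_assigned)) {
        states[t, j] <- NA_integer_
      } else if (characters$kind[j] == "fusion-association") {
        hit <- any(vapply(t_comp, function(u) all(units %in% u), TRUE))
        states[t, j] <- as.integer(hit)
      } else {
        n <- t_counts$n_descendants[t_counts$unit == units]
        n <- if (length(n) == 0) 1L else n
        states[t, j] <- as.integer(n >= characters$min_count[j])
      }
    }
  }
  char_matrix(states, characters)
}

#' Binary character matrix
#'
#' A light container for a taxa-by-characters grid over states
#' `{0, 1, ?}`; `?` is stored as `NA`. Constructed by [build_matrix()],
#' [read_matrix()] or directly from an integer/character matrix.
#'
#' @param states Matrix with taxa as rownames; entries 0, 1 and NA (or the
#'   characters `"0"`, `"1"`, `"?"`).
#' @param characters Optional character metadata tibble (`id`, `kind`,
#'   `label`, ...); defaults to generic `other-discrete` descriptors named
#'   after the matrix columns.
#' @return An object of class `char_matrix` with fields `taxa`,
#'   `characters` and `states`.
#' @export
char_matrix <- function(states, characters = NULL) {
  if (is.character(states)) {
    st <- matrix(NA_integer_, nrow(states), ncol(states), dimnames = dimnames(states))
    st[states == "0"] <- 0L
    st[states == "1"] <- 1L
    bad <- !(states %in% c("0", "1", "?"))
    if (any(bad)) abort("character-matrix states must be 0, 1 or ?")
    states <- st
  }
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) abort("states must have taxa as rownames")
  if (!all(states %in% c(0L, 1L) | is.na(states))) {
    abort("character-matrix states must be 0, 1 or NA (missing)")
  }
  if (is.null(colnames(states)) && ncol(states) > 0) {
    colnames(states) <- paste0("char", seq_len(ncol(states)))
  }
  if (!is.null(colnames(states))) colnames(states) <- unname(colnames(states))
  if (is.null(characters)) {
    characters <- tibble::tibble(
      id = colnames(states) %||% character(0),
      kind = rep("other-discrete", ncol(states)),
      label = colnames(states),
      units = replicate(ncol(states), character(), simplify = FALSE),
      min_count = rep(NA_integer_, ncol(states))
    )
  }
  if (!identical(unname(characters$id), colnames(states) %||% character(0))) {
    abort("character ids must match the state matrix columns")
  }
  all_missing <- apply(states, 2, function(x) all(is.na(x)))
  if (ncol(states) > 0 && any(all_missing)) {
    abort(paste0(
      "character(s) with no observed state: ",
      paste(colnames(states)[all_missing], collapse = ", ")
    ))
  }
  structure(
    list(taxa = rownames(states), characters = characters, states = states),
    class = "char_matrix"
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(
    "<char_matrix> ", length(x$taxa), " taxa x ", ncol(x$states),
    " binary characters\n",
    sep = ""
  )
  cls <- if (ncol(x$states) > 0) classify_characters(x) else NULL
  if (!is.null(cls)) {
    tab <- table(cls$class)
    cat("  ", paste(names(tab), unname(tab), sep = ": ", collapse = ", "), "\n", sep = "")
  }
  cat("  taxa: ", paste(x$taxa, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' @export
as.matrix.char_matrix <- function(x, ...) x$states

#' Long-format view of a character matrix
#'
#' @param x A `char_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `character`, `kind`, `state`
#'   (`"0"`, `"1"` or `"?"`).
#' @export
tidy.char_matrix <- function(x, ...) {
  st <- x$states
  out <- tibble::tibble(
    taxon = rep(rownames(st), times = ncol(st)),
    character = rep(colnames(st), each = nrow(st)),
    state = as.vector(ifelse(is.na(st), "?", as.character(st)))
  )
  out$kind <- x$characters$kind[match(out$character, x$characters$id)]
  out[, c("taxon", "character", "kind", "state")]
}

#' One-row summary of a character matrix
#'
#' @param x A `char_matrix`.
#' @param ... Unused.
#' @return A tibble with taxon/character counts and the informative /
#'   uninformative / constant breakdown.
#' @export
glance.char_matrix <- function(x, ...) {
  cls <- classify_characters(x)
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_characters = ncol(x$states),
    n_informative = sum(cls$class == "parsimony-informative"),
    n_uninformative = sum(cls$class == "autapomorphic/uninformative"),
    n_constant = sum(cls$class == "constant"),
    n_missing_cells = sum(is.na(x$states))
  )
}

#' Classify characters as constant, uninformative or parsimony-informative
#'
#' A binary character is parsimony-informative when each of its states is
#' present in at least two taxa (missing states excluded); variable but not
#' informative characters are autapomorphic/uninformative; the rest are
#' constant over the observed states.
#'
#' @param matrix A `char_matrix`.
#' @return A tibble with columns `id` and `class`.
#' @export
classify_characters <- function(matrix) {
  st <- matrix$states
  cls <- vapply(seq_len(ncol(st)), function(j) {
    x <- st[, j]
    n0 <- sum(x == 0L, na.rm = TRUE)
    n1 <- sum(x == 1L, na.rm = TRUE)
    if (n0 >= 2 && n1 >= 2) {
      "parsimony-informative"
    } else if (n0 >= 1 && n1 >= 1) {
      "autapomorphic/uninformative"
    } else {
      "constant"
    }
  }, "")
  tibble::tibble(id = colnames(st), class = cls)
}

#' Remove one character column from a matrix
#'
#' Returns a new matrix without the named column; the input is unchanged.
#'
#' @param matrix A `char_matrix`.
#' @param id Character id to remove.
#' @return A `char_matrix` with one fewer column.
#' @export
drop_character <- function(matrix, id) {
  j <- match(id, colnames(matrix$states))
  if (is.na(j)) abort(paste0("no character with id '", id, "'"))
  char_matrix(
    matrix$states[, -j, drop = FALSE],
    matrix$characters[-j, , drop = FALSE]
  )
}
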