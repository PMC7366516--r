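# Homology maps: tabular records of chromosome painting results. One row
# assigns a segment of an ancestral chromosome (PAK or GGA coordinates) to
# a region of a descendant (species-local) chromosome.

HOMOLOGY_COLUMNS <- c(
  "taxon", "ancestral_chr", "ancestral_region", "descendant_chr",
  "descendant_region", "evidence", "diploid_number"
)

EVIDENCE_TOKENS <- c("whole-chromosome-paint", "BAC", "reciprocal-paint", "inferred")

new_homology_map <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("homology_map", class(tibble::tibble()))
  df
}

validate_homology_map <- function(df, source = "homology map") {
  missing_cols <- setdiff(HOMOLOGY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      source, ": missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  line <- function(i) {
    if (!is.null(df$.line)) df$.line[i] else i
  }
  bad_region <- which(!(df$ancestral_region %in% REGION_TOKENS) |
    !(df$descendant_region %in% REGION_TOKENS))
  if (length(bad_region) > 0) {
    i <- bad_region[1]
    abort(paste0(
      source, ", line ", line(i), ": unknown region token '",
      df$ancestral_region[i], "'/'", df$descendant_region[i],
      "' (expected one of ", paste(REGION_TOKENS, collapse = ", "), ")"
    ))
  }
  anc <- parse_chr_label(df$ancestral_chr)
  bad_anc <- which(is.na(anc$scheme))
  if (length(bad_anc) > 0) {
    i <- bad_anc[1]
    abort(paste0(
      source, ", line ", line(i), ": ancestral label '",
      df$ancestral_chr[i], "' is not PAK/GGA/MIC/micro"
    ))
  }
  dn <- df$diploid_number
  if (any(is.na(dn) | dn <= 0 | dn %% 2 != 0)) {
    i <- which(is.na(dn) | dn <= 0 | dn %% 2 != 0)[1]
    abort(paste0(
      source, ", line ", line(i), ": diploid number must be a positive even",
      " integer, got ", dn[i]
    ))
  }
  per_taxon_2n <- tapply(df$diploid_number, df$taxon, function(x) length(unique(x)))
  if (any(per_taxon_2n > 1)) {
    abort(paste0(
      source, ": taxon ", names(which(per_taxon_2n > 1))[1],
      " has conflicting diploid numbers"
    ))
  }
  # a descendant chromosome may carry a given (ancestral chr, region) once
  key <- paste(df$taxon, df$ancestral_chr, df$ancestral_region, df$descendant_chr)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    i <- dup[1]
    abort(paste0(
      source, ", line ", line(i), ": duplicate assignment of ",
      df$ancestral_chr[i], " (", df$ancestral_region[i], ") to ",
      df$descendant_chr[i], " for taxon ", df$taxon[i]
    ))
  }
  invisible(df)
}

#' Read a homology-map TSV
#'
#' Parses a UTF-8 tab-separated homology table with columns `taxon`,
#' `ancestral_chr` (e.g. `"GGA4"`), `ancestral_region` (one of `whole`, `p`,
#' `q`, `pq`, `prox_q`, `dist_q`, `unknown`), `descendant_chr`,
#' `descendant_region`, `evidence` and `diploid_number`. Lines starting with
#' `#` are comments; extra columns (e.g. `provenance`) are preserved. Rows
#' for all taxa live in one file; the result is one tibble, subsettable by
#' taxon.
#'
#' @param path Path to the TSV file.
#' @param convert_to Optionally `"PAK"` or `"GGA"` to normalize ancestral
#'   labels on read; `NULL` keeps them as written.
#' @return A `homology_map` tibble (row order preserved).
#' @export
#' @examples
#' mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
#' dplyr::count(mmo, ancestral_chr)
parse_homology_tsv <- function(path, convert_to = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(paste0(path, ": homology table has a header but no assignments"))
    out <- tibble::as_tibble(raw)
    out$diploid_number <- integer(0)
    return(new_homology_map(out[HOMOLOGY_COLUMNS]))
  }
  raw$diploid_number <- suppressWarnings(as.integer(raw$diploid_number))
  raw$.line <- seq_len(nrow(raw))
  validate_homology_map(raw, source = path)
  raw$.line <- NULL
  map <- new_homology_map(raw)
  if (!is.null(convert_to)) map <- convert_ancestral_scheme(map, convert_to)
  map
}

#' Write a homology map back to TSV
#'
#' Inverse of [parse_homology_tsv()]; `parse_homology_tsv(write_homology_tsv(m))`
#' reproduces `m` exactly.
#'
#' @param map A homology map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_tsv <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map), path, progress = FALSE)
  invisible(path)
}

single_taxon <- function(map, taxon = NULL, caller = "this function") {
  taxa <- unique(map$taxon)
  if (is.null(taxon)) {
    if (length(taxa) > 1) {
      abort(paste0(
        caller, " needs a single taxon; the map has ",
        length(taxa), " - pass `taxon = `"
      ))
    }
    return(map)
  }
  map[map$taxon == taxon, , drop = FALSE]
}

#' Count descendant chromosomes homologous to an ancestral chromosome
#'
#' The number of distinct descendant chromosomes (arm and region qualifiers
#' ignored) that carry painted homology to the given ancestral chromosome.
#' Two or more means the ancestral chromosome is fissioned in this
#' karyotype; zero means it was not assigned (not an error).
#'
#' @param map A homology map.
#' @param ancestral Ancestral chromosome label, e.g. `"GGA1"`. Arm
#'   qualifiers on the map rows are ignored, so `"GGA4"` matches both arms.
#' @param taxon Taxon to count for; may be omitted for single-taxon maps.
#' @return A non-negative integer.
#' @export
#' @examples
#' mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
#' count_descendant_pairs(mmo, "GGA1")
count_descendant_pairs <- function(map, ancestral, taxon = NULL) {
  m <- single_taxon(map, taxon, "count_descendant_pairs()")
  rows <- m[m$ancestral_chr == ancestral, , drop = FALSE]
  length(unique(rows$descendant_chr))
}

#' Per-taxon descendant counts for every ancestral chromosome
#'
#' Tidy companion of [count_descendant_pairs()]: one row per
#' (taxon, ancestral chromosome).
#'
#' @param map A homology map.
#' @return A tibble with columns `taxon`, `ancestral_chr`, `n_descendants`.
#' @export
descendant_pair_counts <- function(map) {
  tibble::as_tibble(map) |>
    dplyr::distinct(.data$taxon, .data$ancestral_chr, .data$descendant_chr) |>
    dplyr::count(.data$taxon, .data$ancestral_chr, name = "n_descendants")
}

#' Detect fusion events in a homology map
#'
#' A fusion is reported for every descendant chromosome that carries
#' homologies to two or more distinct ancestral chromosomes (syntenic
#' association). Detection works at whole-chromosome resolution: arm and
#' region qualifiers are dropped on both sides, so the two arms of GGA4
#' count as one ancestral chromosome here (use PAK coordinates, where they
#' are PAK4 and PAK10, if arm-level associations matter).
#'
#' @param map A homology map (one or several taxa).
#' @return A tibble with columns `taxon`, `kind` (`"fusion"`), `locus`
#'   (descendant chromosome), `participants` (list column of sorted
#'   ancestral labels) and `n_participants`, ordered by taxon and ascending
#'   descendant chromosome number.
#' @export
#' @examples
#' mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
#' detect_fusions(mmo)
detect_fusions <- function(map) {
  df <- tibble::as_tibble(map)
  if (nrow(df) == 0) {
    return(tibble::tibble(
      taxon = character(), kind = character(), locus = character(),
      participants = list(), n_participants = integer()
    ))
  }
  out <- df |>
    dplyr::distinct(.data$taxon, .data$descendant_chr, .data$ancestral_chr) |>
    dplyr::group_by(.data$taxon, .data$descendant_chr) |>
    dplyr::summarise(
      participants = list(sort(unique(.data$ancestral_chr))),
      n_participants = length(unique(.data$ancestral_chr)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_participants >= 2) |>
    dplyr::mutate(
      kind = "fusion",
      locus = .data$descendant_chr,
      .num = descendant_number(.data$descendant_chr)
    ) |>
    dplyr::arrange(.data$taxon, .data$.num, .data$locus) |>
    dplyr::select("taxon", "kind", "locus", "participants", "n_participants")
  out
}

#' Detect fission events in a homology map
#'
#' A fission is reported for every ancestral chromosome whose homology is
#' spread over two or more distinct descendant chromosomes, annotated with
#' the descendant count. Same whole-chromosome resolution caveats as
#' [detect_fusions()].
#'
#' @param map A homology map.
#' @return A tibble with columns `taxon`, `kind` (`"fission"`),
#'   `ancestral_chr`, `n_descendants` and `descendants` (list column).
#' @export
#' @examples
#' mmo <- parse_homology_tsv(karyotree_example("tables2_mmo.tsv"))
#' detect_fissions(mmo)
detect_fissions <- function(map) {
  df <- tibble::as_tibble(map)
  if (nrow(df) == 0) {
    return(tibble::tibble(
      taxon = character(), kind = character(), ancestral_chr = character(),
      n_descendants = integer(), descendants = list()
    ))
  }
  df |>
    dplyr::distinct(.data$taxon, .data$ancestral_chr, .data$descendant_chr) |>
    dplyr::group_by(.data$taxon, .data$ancestral_chr) |>
    dplyr::summarise(
      descendants = list(sort(unique(.data$descendant_chr))),
      n_descendants = length(unique(.data$descendant_chr)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_descendants >= 2) |>
    dplyr::mutate(kind = "fission", .key = unit_sort_key(.data$ancestral_chr)) |>
    dplyr::arrange(.data$taxon, .data$.key, .data$ancestral_chr) |>
    dplyr::select("taxon", "kind", "ancestral_chr", "n_descendants", "descendants")
}
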