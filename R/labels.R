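# Chromosome label handling.
#
# Ancestral chromosomes are named either in PAK coordinates (Putative Avian
# Ancestral Karyotype, PAK1..PAK15) or in GGA coordinates (chicken
# chromosomes). The two schemes interconvert by a fixed table in which the
# arms of chicken chromosome 4 are separate ancestral chromosomes
# (GGA4q = PAK4, GGA4p = PAK10). Identified microchromosomes keep their
# chicken number (GGA17..GGA28 from BAC mapping) or carry simulator labels
# MIC1, MIC2, ...; the bare token "micro" denotes an unidentified
# microchromosome and never takes part in character coding.

REGION_TOKENS <- c("whole", "p", "q", "pq", "prox_q", "dist_q", "unknown")

#' Conversion table between PAK and GGA ancestral chromosome labels
#'
#' PAK1-11 and PAK13-15 correspond to GGA1-GGA3, GGA4q, GGA5-GGA9, GGA4p,
#' GGA10 and GGA12-GGA14 respectively; PAK12 corresponds to GGA11.
#'
#' @return A tibble with columns `pak`, `gga_chr`, `gga_region`.
#' @export
pak_gga_table <- function() {
  tibble::tibble(
    pak = paste0("PAK", 1:15),
    gga_chr = paste0("GGA", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 4, 10, 11, 12, 13, 14)),
    gga_region = c(rep("whole", 3), "q", rep("whole", 5), "p", rep("whole", 5))
  )
}

# Split a label like "GGA4", "PAK7", "MIC12" or "micro" into scheme/number.
parse_chr_label <- function(x) {
  scheme <- dplyr::case_when(
    x == "micro" ~ "micro",
    stringr::str_detect(x, "^PAK\\d+$") ~ "PAK",
    stringr::str_detect(x, "^GGA\\d+$") ~ "GGA",
    stringr::str_detect(x, "^MIC\\d+$") ~ "MIC",
    TRUE ~ NA_character_
  )
  number <- ifelse(scheme %in% c("PAK", "GGA", "MIC"),
    suppressWarnings(as.integer(stringr::str_extract(x, "\\d+"))),
    NA_integer_
  )
  tibble::tibble(label = x, scheme = scheme, number = number)
}

# Map (ancestral_chr, ancestral_region) rows in GGA coordinates to PAK
# coordinate rows. GGA4 splits by arm; a whole/pq GGA4 expands to both
# PAK4 and PAK10. Labels already in PAK (or MIC/micro/other) pass through.
# Returns a data frame with possibly more rows than the input; the column
# `unit` holds the PAK-level ancestral unit used for character coding.
ancestral_to_pak_units <- function(df) {
  tab <- pak_gga_table()
  one <- function(chr, region) {
    if (stringr::str_detect(chr, "^PAK\\d+$") ||
      stringr::str_detect(chr, "^MIC\\d+$") || chr == "micro") {
      return(tibble::tibble(unit = chr, unit_region = region))
    }
    if (!stringr::str_detect(chr, "^GGA\\d+$")) {
      abort(paste0("cannot convert ancestral label '", chr, "' to PAK units"))
    }
    hits <- tab[tab$gga_chr == chr, ]
    if (nrow(hits) == 0) {
      # identified chicken microchromosome outside the PAK table (BACs)
      return(tibble::tibble(unit = chr, unit_region = region))
    }
    if (nrow(hits) == 1) {
      return(tibble::tibble(unit = hits$pak, unit_region = region))
    }
    # GGA4: pick the arm, or both for whole/pq/unknown
    if (region %in% c("q", "prox_q", "dist_q")) {
      tibble::tibble(unit = hits$pak[hits$gga_region == "q"], unit_region = "whole")
    } else if (region == "p") {
      tibble::tibble(unit = hits$pak[hits$gga_region == "p"], unit_region = "whole")
    } else {
      tibble::tibble(unit = hits$pak, unit_region = "whole")
    }
  }
  out <- df
  expanded <- purrr::map2(df$ancestral_chr, df$ancestral_region, one)
  idx <- rep(seq_len(nrow(df)), vapply(expanded, nrow, 1L))
  out <- out[idx, , drop = FALSE]
  exp_df <- dplyr::bind_rows(expanded)
  out$unit <- exp_df$unit
  out$unit_region <- exp_df$unit_region
  out
}

#' Convert ancestral labels of a homology map between PAK and GGA schemes
#'
#' @param map A homology map (see [parse_homology_tsv()]).
#' @param to Target scheme, `"PAK"` or `"GGA"`.
#' @return A homology map with converted `ancestral_chr`/`ancestral_region`.
#' @export
convert_ancestral_scheme <- function(map, to = c("PAK", "GGA")) {
  to <- match.arg(to)
  tab <- pak_gga_table()
  if (to == "PAK") {
    conv <- ancestral_to_pak_units(map)
    conv$ancestral_chr <- conv$unit
    conv$ancestral_region <- conv$unit_region
    conv$unit <- NULL
    conv$unit_region <- NULL
    out <- conv
  } else {
    one <- function(chr, region) {
      if (!stringr::str_detect(chr, "^PAK\\d+$")) {
        return(c(chr, region))
      }
      hit <- tab[tab$pak == chr, ]
      reg <- if (hit$gga_region == "whole") region else hit$gga_region
      c(hit$gga_chr, reg)
    }
    pieces <- purrr::map2(map$ancestral_chr, map$ancestral_region, one)
    out <- map
    out$ancestral_chr <- vapply(pieces, `[`, "", 1)
    out$ancestral_region <- vapply(pieces, `[`, "", 2)
  }
  new_homology_map(out)
}

# Sort key for ancestral units: PAK numbers first, then chicken
# microchromosome numbers (GGA17+), then simulator micros.
unit_sort_key <- function(unit) {
  p <- parse_chr_label(unit)
  key <- dplyr::case_when(
    p$scheme == "PAK" ~ p$number,
    p$scheme == "GGA" ~ p$number + 0L,
    p$scheme == "MIC" ~ p$number + 1000L,
    TRUE ~ 100000L
  )
  as.integer(key)
}

# Numeric part of a species-local descendant chromosome label ("MMO13",
# "C4", "15"); NA for non-numbered labels such as "micro".
descendant_number <- function(x) {
  suppressWarnings(as.integer(stringr::str_extract(x, "\\d+")))
}
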