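# NEXUS / PHYLIP serialization for binary character matrices.
#
# NEXUS: a DATA block with FORMAT datatype=standard symbols="01" missing=?
# gap=-; CHARLABELS carries the character labels. Both sequential and
# interleaved MATRIX sections are read. PHYLIP: relaxed dialect, names
# whitespace-delimited.

#' Write a character matrix to NEXUS or PHYLIP
#'
#' @param matrix A `char_matrix`.
#' @param path Output path.
#' @param format `"nexus"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("nexus", "phylip")) {
  format <- match.arg(format)
  st <- matrix$states
  rows <- apply(st, 1, function(x) paste(ifelse(is.na(x), "?", x), collapse = ""))
  if (format == "nexus") {
    labels <- gsub("'", "", matrix$characters$id)
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
      if (ncol(st) > 0) {
        c("  CHARLABELS", paste0("    ", paste0("'", labels, "'", collapse = " "), ";"))
      },
      "  MATRIX",
      sprintf("    %-12s %s", rownames(st), rows),
      "  ;",
      "END;"
    )
  } else {
    lines <- c(
      sprintf("%d %d", nrow(st), ncol(st)),
      sprintf("%-12s %s", rownames(st), rows)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

parse_state_row <- function(x, path) {
  chars <- strsplit(gsub("\\s", "", x), "")[[1]]
  bad <- setdiff(unique(chars), c("0", "1", "?", "-"))
  if (length(bad) > 0) {
    abort(paste0(path, ": unexpected state symbol(s): ", paste(bad, collapse = " ")))
  }
  out <- rep(NA_integer_, length(chars))
  keep <- chars %in% c("0", "1")
  out[keep] <- as.integer(chars[keep])
  out
}

read_nexus_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("\\[[^]]*\\]", "", txt) # strip simple comments
  if (!any(grepl("^#NEXUS", txt, ignore.case = TRUE))) {
    abort(paste0(path, ": not a NEXUS file (missing #NEXUS header)"))
  }
  joined <- paste(txt, collapse = "\n")
  dims <- regmatches(joined, regexpr("DIMENSIONS[^;]*;", joined, ignore.case = TRUE))
  if (length(dims) == 0) abort(paste0(path, ": malformed DATA block: no DIMENSIONS"))
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_)) {
    abort(paste0(path, ": malformed DIMENSIONS statement: ", dims))
  }
  labels <- NULL
  lab <- regmatches(joined, regexpr("CHARLABELS[^;]*;", joined, ignore.case = TRUE))
  if (length(lab) == 1) {
    body <- sub(";$", "", sub("^CHARLABELS", "", lab, ignore.case = TRUE))
    labels <- regmatches(body, gregexpr("'[^']*'|[^\\s']+", body, perl = TRUE))[[1]]
    labels <- gsub("^'|'$", "", labels)
  }
  # MATRIX section: from the MATRIX keyword to the next line-terminating ;
  mstart <- grep("^\\s*MATRIX\\s*$", txt, ignore.case = TRUE)
  if (length(mstart) == 0) abort(paste0(path, ": malformed DATA block: no MATRIX"))
  mend <- grep("^\\s*;\\s*$", txt)
  mend <- mend[mend > mstart[1]][1]
  if (is.na(mend)) abort(paste0(path, ": MATRIX section not terminated by ';'"))
  body <- txt[(mstart[1] + 1):(mend - 1)]
  body <- body[nzchar(trimws(body))]
  acc <- list()
  for (ln in body) {
    ln <- trimws(ln)
    name <- sub("^('[^']*'|\\S+).*", "\\1", ln)
    states <- trimws(substring(ln, nchar(name) + 1))
    name <- gsub("^'|'$", "", name)
    acc[[name]] <- paste0(acc[[name]] %||% "", gsub("\\s", "", states))
  }
  if (length(acc) != ntax) {
    abort(paste0(
      path, ": MATRIX has ", length(acc), " taxa but DIMENSIONS declares ", ntax
    ))
  }
  rows <- lapply(acc, parse_state_row, path = path)
  if (length(unique(lengths(rows))) > 1) {
    abort(paste0(path, ": MATRIX rows have unequal character counts"))
  }
  st <- do.call(rbind, rows)
  rownames(st) <- names(acc)
  if (ncol(st) != nchar_) {
    abort(paste0(
      path, ": rows have ", ncol(st), " characters but DIMENSIONS declares ", nchar_
    ))
  }
  if (!is.null(labels)) {
    if (length(labels) != nchar_) {
      abort(paste0(path, ": CHARLABELS count does not match NCHAR"))
    }
    colnames(st) <- make.unique(labels)
  }
  st
}

read_phylip_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  hdr <- strsplit(trimws(txt[1]), "\\s+")[[1]]
  if (length(hdr) < 2) abort(paste0(path, ": malformed PHYLIP header"))
  ntax <- as.integer(hdr[1])
  nchar_ <- as.integer(hdr[2])
  body <- txt[-1]
  if (length(body) != ntax) {
    abort(paste0(path, ": ", length(body), " rows but header declares ", ntax, " taxa"))
  }
  names <- sub("^(\\S+).*", "\\1", trimws(body))
  states <- sub("^\\S+\\s*", "", trimws(body))
  rows <- lapply(states, parse_state_row, path = path)
  if (any(lengths(rows) != nchar_)) {
    bad <- which(lengths(rows) != nchar_)[1]
    abort(paste0(
      path, ": row ", bad, " has ", lengths(rows)[bad],
      " characters but the header declares ", nchar_
    ))
  }
  st <- do.call(rbind, rows)
  rownames(st) <- names
  st
}

#' Read a character matrix from NEXUS or PHYLIP
#'
#' Lossless counterpart of [write_matrix()]: taxa, character labels (NEXUS
#' CHARLABELS) and states `{0, 1, ?}` round-trip exactly. Interleaved NEXUS
#' matrices are supported.
#'
#' @param path Input path.
#' @param format `"nexus"` or `"phylip"`.
#' @return A `char_matrix`.
#' @export
read_matrix <- function(path, format = c("nexus", "phylip")) {
  format <- match.arg(format)
  st <- if (format == "nexus") read_nexus_matrix(path) else read_phylip_matrix(path)
  if (is.null(colnames(st))) {
    colnames(st) <- paste0("char", seq_len(ncol(st)))
  }
  ids <- colnames(st)
  characters <- tibble::tibble(
    id = ids,
    kind = rep("other-discrete", length(ids)),
    label = ids,
    units = replicate(length(ids), character(), simplify = FALSE),
    min_count = rep(NA_integer_, length(ids))
  )
  char_matrix(st, characters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
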