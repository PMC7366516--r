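# End-to-end workflow: homology maps (or an explicit matrix) -> character
# coding -> parsimony search -> fit statistics -> bootstrap -> outgroup
# rooting -> consensus, with every intermediate archived to disk so each
# reported number can be recomputed from the files.

#' Configuration for a pipeline run
#'
#' @param maps_path Path(s) to homology-map TSV files (coding mode
#'   `"auto"`).
#' @param matrix_path Path to an explicit character matrix (coding mode
#'   `"explicit-matrix"`).
#' @param matrix_format Format of `matrix_path`, `"nexus"` or `"phylip"`.
#' @param coding `"auto"` (code characters from the maps) or
#'   `"explicit-matrix"`.
#' @param taxa Optional subset/order of taxa to analyse.
#' @param search A [search_config()].
#' @param bootstrap_replicates Bootstrap replicate count (0 disables).
#' @param outgroup Character vector of outgroup taxa (may be empty).
#' @param seed Integer seed; mandatory, it drives every stochastic stage.
#' @param out_dir Output directory for archived intermediates.
#' @return A `run_config` object.
#' @export
run_config <- function(maps_path = NULL, matrix_path = NULL,
                       matrix_format = c("nexus", "phylip"),
                       coding = c("auto", "explicit-matrix"),
                       taxa = NULL,
                       search = search_config(),
                       bootstrap_replicates = 1000,
                       outgroup = character(),
                       seed,
                       out_dir = tempfile("karyotree_run_")) {
  coding <- match.arg(coding)
  matrix_format <- match.arg(matrix_format)
  if (missing(seed) || is.null(seed)) {
    abort("run_config() requires an explicit seed")
  }
  if (coding == "auto" && is.null(maps_path)) {
    abort("coding = 'auto' requires maps_path")
  }
  if (coding == "explicit-matrix" && is.null(matrix_path)) {
    abort("coding = 'explicit-matrix' requires matrix_path")
  }
  structure(
    list(
      maps_path = maps_path, matrix_path = matrix_path,
      matrix_format = matrix_format, coding = coding, taxa = taxa,
      search = search, bootstrap_replicates = bootstrap_replicates,
      outgroup = outgroup, seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full inference pipeline
#'
#' Executes coding (or matrix loading), parsimony search, fit statistics,
#' bootstrap, outgroup rooting and consensus, archiving the matrix
#' (NEXUS), the MP trees and consensus (Newick) and the report (JSON and
#' text) under `config$out_dir`. Deterministic for a fixed config: two
#' runs give identical reports apart from the timestamp.
#'
#' @param config A [run_config()].
#' @return A `karyotree_report` object (also written to disk).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  matrix <- stage("coding", {
    if (config$coding == "auto") {
      maps <- dplyr::bind_rows(lapply(config$maps_path, parse_homology_tsv))
      if (!is.null(config$taxa)) {
        maps <- maps[maps$taxon %in% config$taxa, , drop = FALSE]
        maps$taxon <- factor(maps$taxon, levels = config$taxa)
        maps <- maps[order(maps$taxon), , drop = FALSE]
        maps$taxon <- as.character(maps$taxon)
      }
      build_matrix(new_homology_map(maps))
    } else {
      m <- read_matrix(config$matrix_path, config$matrix_format)
      if (!is.null(config$taxa)) {
        st <- m$states[config$taxa, , drop = FALSE]
        m <- char_matrix(st, m$characters)
      }
      m
    }
  })
  if (length(config$outgroup) > 0 && !all(config$outgroup %in% matrix$taxa)) {
    abort("outgroup taxa missing from the matrix")
  }
  write_matrix(matrix, file.path(config$out_dir, "matrix.nex"), "nexus")
  classes <- classify_characters(matrix)

  method <- resolve_method(config$search, length(matrix$taxa))
  result <- stage("search", {
    if (method == "exhaustive") {
      exhaustive_search(matrix, max_taxa = config$search$max_exhaustive_taxa)
    } else {
      heuristic_search(
        matrix,
        n_addition_replicates = config$search$n_addition_replicates,
        seed = config$seed
      )
    }
  })
  ape::write.tree(result$mp_trees, file.path(config$out_dir, "mp_trees.nwk"))

  boots <- NULL
  if (config$bootstrap_replicates > 0) {
    boots <- stage("bootstrap", {
      bootstrap(
        matrix,
        replicates = config$bootstrap_replicates,
        seed = config$seed, search = config$search
      )
    })
  }

  consensus <- stage("consensus", strict_consensus(result$mp_trees))
  rooted <- NULL
  if (length(config$outgroup) > 0) {
    rooted <- stage("rooting", root_on_outgroup(consensus, config$outgroup))
    ape::write.tree(rooted, file.path(config$out_dir, "consensus_rooted.nwk"))
  }
  ape::write.tree(consensus, file.path(config$out_dir, "consensus.nwk"))
  if (!is.null(boots)) {
    ape::write.tree(boots$consensus, file.path(config$out_dir, "bootstrap_consensus.nwk"))
  }

  report <- structure(
    list(
      n_taxa = length(matrix$taxa),
      n_characters = ncol(matrix$states),
      n_informative = sum(classes$class == "parsimony-informative"),
      n_uninformative = sum(classes$class == "autapomorphic/uninformative"),
      n_constant = sum(classes$class == "constant"),
      n_mp_trees = length(result$mp_trees),
      length = result$length,
      ci = result$ci, hi = result$hi, ri = result$ri,
      search_method = method,
      bootstrap_replicates = if (is.null(boots)) 0L else boots$replicates,
      supports = if (is.null(boots)) NULL else boots$supports,
      outgroup = config$outgroup,
      provenance = list(
        package_version = as.character(utils::packageVersion("karyotree")),
        seed = config$seed,
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "karyotree_report"
  )
  json <- report
  json$supports <- if (!is.null(report$supports)) {
    as.list(setNames(report$supports$support, report$supports$clade))
  }
  jsonlite::write_json(
    unclass(json), file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  report
}

format_report <- function(x) {
  c(
    "karyotree pipeline report",
    sprintf("matrix: %d taxa x %d characters", x$n_taxa, x$n_characters),
    sprintf(
      "characters: %d informative, %d uninformative, %d constant",
      x$n_informative, x$n_uninformative, x$n_constant
    ),
    sprintf(
      "parsimony (%s): %d MP tree(s), length %d, CI %.4f, HI %.4f, RI %s",
      x$search_method, x$n_mp_trees, x$length, x$ci, x$hi,
      ifelse(is.na(x$ri), "undefined", sprintf("%.4f", x$ri))
    ),
    if (x$bootstrap_replicates > 0) {
      c(
        sprintf("bootstrap: %d replicates", x$bootstrap_replicates),
        sprintf(
          "  %s: %.1f", utils::head(x$supports$clade, 12),
          utils::head(x$supports$support, 12)
        )
      )
    },
    sprintf("seed: %d", x$provenance$seed)
  )
}

#' @export
print.karyotree_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Compare an inferred tree against a reference topology
#'
#' @param report_tree,reference Trees (`phylo`) on the same leaf set.
#' @return A list with the Robinson-Foulds distance `rf` and
#'   `shared_clades`, the clades common to both trees.
#' @export
compare_trees <- function(report_tree, reference) {
  if (!setequal(report_tree$tip.label, reference$tip.label)) {
    abort("compare_trees() needs trees on the same leaf set")
  }
  a <- tree_bipartitions(report_tree)
  b <- tree_bipartitions(reference)
  list(
    rf = length(setdiff(a, b)) + length(setdiff(b, a)),
    shared_clades = lapply(intersect(a, b), function(k) {
      strsplit(k, "|", fixed = TRUE)[[1]]
    })
  )
}
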