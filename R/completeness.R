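#' Load or construct a single-copy marker set
#'
#' A marker set is the list of single-copy genes whose presence in a
#' genome bin estimates its completeness. Two conventional set sizes are
#' bundled: 112 genes essential in bacteria and 53 genes core to
#' archaea. The bundled files carry placeholder marker identifiers
#' (`bac_essential_001`, `arc_core_001`, ...) generated with the
#' package -- the completeness computation depends only on identifier
#' matching, not on which profile each identifier denotes -- so supply
#' your own file to use real HMM accessions.
#'
#' @param x `"bacteria_112"`, `"archaea_53"`, a path to a marker-set
#'   file (first line `#name=<set name>`, then one marker id per line),
#'   or a character vector of marker ids.
#' @param name Set name when `x` is a vector of ids.
#' @return A `marker_set`: list with `name`, `markers`, `size`.
#' @export
marker_set <- function(x, name = NULL) {
  if (length(x) == 1L && x %in% c("bacteria_112", "archaea_53")) {
    path <- system.file("extdata",
      paste0("markers_", x, "_synthetic_ids.txt"),
      package = "brinemag"
    )
    return(marker_set(path))
  }
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x)
    nm <- if (startsWith(lines[1], "#name=")) sub("^#name=", "", lines[1]) else basename(x)
    ids <- lines[!startsWith(lines, "#") & nzchar(lines)]
    return(marker_set(ids, name = nm))
  }
  ids <- unique(as.character(x))
  structure(
    list(name = name %||% "custom", markers = ids, size = length(ids)),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set>", x$name, "with", x$size, "markers\n")
  invisible(x)
}

#' Tier marker hits into loose and strict presence
#'
#' From the tabular output of a profile-HMM search of a bin's predicted
#' genes against a marker set, a marker is *loosely* present when it has
#' at least one hit at `evalue <= max_evalue`, and *strictly* present
#' when such a hit additionally has both hit coverage and query coverage
#' above `min_cov` (the "best annotations"). Strict presence implies
#' loose presence. Multi-copy markers count once.
#'
#' @param hits Tibble with columns `marker_id`, `gene_id`, `evalue`,
#'   `hcov`, `qcov` (coverages as fractions), e.g. from
#'   [read_marker_hits()].
#' @param markers A [marker_set()].
#' @param max_evalue E-value cutoff (default 1e-5).
#' @param min_cov Coverage threshold, exclusive (default 0.80: coverage
#'   must exceed 80%).
#' @return A tibble with one row per marker of the set: `marker_id`,
#'   `loose`, `strict` (logicals). Hits naming markers outside the set
#'   are dropped with a warning.
#' @export
evaluate_markers <- function(hits, markers, max_evalue = 1e-5, min_cov = 0.80) {
  stopifnot(is.data.frame(hits), inherits(markers, "marker_set"))
  unknown <- setdiff(unique(hits$marker_id), markers$markers)
  if (length(unknown) > 0L) {
    warn(paste0(
      "ignoring hits to ", length(unknown),
      " marker id(s) outside the set: ", paste(head(unknown, 3), collapse = ", "),
      if (length(unknown) > 3) ", ..."
    ))
    hits <- hits[hits$marker_id %in% markers$markers, , drop = FALSE]
  }
  pass_e <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  strict_ids <- unique(pass_e$marker_id[pass_e$hcov > min_cov & pass_e$qcov > min_cov])
  tibble::tibble(
    marker_id = markers$markers,
    loose = markers$markers %in% unique(pass_e$marker_id),
    strict = markers$markers %in% strict_ids
  )
}

#' Completeness bounds from tiered marker presence
#'
#' The coverage-filtered (strict) detections give the lower completeness
#' bound and all e-value-passing (loose) detections the upper bound:
#' the strict filter can only shrink the detected set. `swap_bounds`
#' reverses the reading.
#'
#' @param evaluated Tibble from [evaluate_markers()].
#' @param markers The [marker_set()] used.
#' @param swap_bounds Use loose for the lower and strict for the upper
#'   bound instead (default `FALSE`).
#' @return A one-row tibble `n_strict`, `n_loose`, `set_size`,
#'   `lower_pct`, `upper_pct`, `label` (the conventional
#'   `"lower--upper"` display string, one decimal).
#' @examples
#' ms <- marker_set(sprintf("m%02d", 1:53), name = "archaea")
#' ev <- tibble::tibble(
#'   marker_id = ms$markers,
#'   loose = seq_len(53) <= 45, strict = seq_len(53) <= 42
#' )
#' completeness_bounds(ev, ms)
#' @export
completeness_bounds <- function(evaluated, markers, swap_bounds = FALSE) {
  stopifnot(is.data.frame(evaluated), inherits(markers, "marker_set"))
  n_strict <- sum(evaluated$strict)
  n_loose <- sum(evaluated$loose)
  stopifnot(n_strict <= n_loose)
  lower <- 100 * n_strict / markers$size
  upper <- 100 * n_loose / markers$size
  if (swap_bounds) {
    tmp <- lower
    lower <- upper
    upper <- tmp
  }
  tibble::tibble(
    n_strict = n_strict, n_loose = n_loose, set_size = markers$size,
    lower_pct = lower, upper_pct = upper,
    label = sprintf("%.1f–%.1f", lower, upper)
  )
}

#' Read a profile-HMM domain-table style marker hit file
#'
#' Five tab-separated columns: `marker_id`, `gene_id`, `evalue`, `hcov`,
#' `qcov` (coverages as fractions). A header line starting with `#` is
#' skipped.
#'
#' @param path Path to the TSV file.
#' @return A typed tibble.
#' @export
read_marker_hits <- function(path) {
  stopifnot(file.exists(path))
  readr::read_tsv(
    path,
    comment = "#",
    col_names = c("marker_id", "gene_id", "evalue", "hcov", "qcov"),
    col_types = "ccddd", progress = FALSE
  )
}
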