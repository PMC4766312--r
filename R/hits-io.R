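#' Read a tabular similarity-search hit table
#'
#' Parses the 12-column tabular output of standard similarity-search
#' tools (query, subject, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, e-value, bit score) or
#' an extended 14-column layout with two extra trailing columns giving
#' query and hit coverage as fractions. The dialect is auto-detected from
#' the column count unless given.
#'
#' When the standard layout is read and `query_lengths` / `subject_lengths`
#' are supplied (named vectors or two-column data frames), `qcov` and
#' `hcov` are computed as alignment span over sequence length; otherwise
#' they are `NA` (absent).
#'
#' @param path Path to a tab-separated hit table (no header).
#' @param dialect `"auto"` (default), `"standard"` (12 columns) or
#'   `"extended"` (14 columns).
#' @param query_lengths,subject_lengths Optional sequence lengths used to
#'   derive coverages for the standard dialect: either a named numeric
#'   vector or a data frame whose first two columns are id and length.
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `qcov`, `hcov`.
#' @export
read_hits <- function(path, dialect = c("auto", "standard", "extended"),
                      query_lengths = NULL, subject_lengths = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols12 <- c(
    "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
    "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 12L)),
      c(cols12, "qcov", "hcov")
    ))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  want <- switch(dialect, standard = 12L, extended = 14L, auto = ncol[1])
  if (dialect == "auto" && !want %in% c(12L, 14L)) {
    abort(paste0("line 1: expected 12 or 14 columns, found ", want))
  }
  bad <- which(ncol != want)
  if (length(bad) > 0L) {
    abort(paste0("malformed hit-table row at line ", bad[1], ": expected ",
                 want, " columns, found ", ncol[bad[1]]))
  }
  m <- do.call(rbind, fields)
  num <- function(j, what, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(m[, j]))
    bad <- is.na(x) & !(allow_na & m[, j] %in% c("NA", "."))
    if (any(bad)) {
      abort(paste0("malformed hit-table row at line ", which(bad)[1],
                   ": non-numeric ", what))
    }
    x
  }
  hits <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "identity"), aln_length = num(4, "alignment length"),
    mismatches = num(5, "mismatches"), gap_opens = num(6, "gap opens"),
    qstart = num(7, "qstart"), qend = num(8, "qend"),
    sstart = num(9, "sstart"), send = num(10, "send"),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore")
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    abort("pct_identity outside [0,100]")
  }
  if (want == 14L) {
    hits$qcov <- num(13, "qcov", allow_na = TRUE)
    hits$hcov <- num(14, "hcov", allow_na = TRUE)
    if (any(hits$qcov < 0 | hits$qcov > 1 | hits$hcov < 0 | hits$hcov > 1,
            na.rm = TRUE)) {
      abort("coverage columns must be fractions in [0,1]")
    }
  } else {
    len_of <- function(tbl, ids) {
      if (is.null(tbl)) return(rep(NA_real_, length(ids)))
      if (is.data.frame(tbl)) tbl <- setNames(as.numeric(tbl[[2]]), tbl[[1]])
      unname(tbl[ids])
    }
    hits$qcov <- abs(hits$qend - hits$qstart) + 1
    hits$qcov <- hits$qcov / len_of(query_lengths, hits$query_id)
    hits$hcov <- abs(hits$send - hits$sstart) + 1
    hits$hcov <- hits$hcov / len_of(subject_lengths, hits$subject_id)
  }
  hits
}

#' Write hits in 12- or 14-column tabular form
#'
#' @param hits A tibble as returned by [read_hits()].
#' @param path Output path.
#' @param extended Write the 14-column layout with `qcov`/`hcov`?
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, extended = FALSE) {
  cols <- c(
    "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
    "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  if (extended) cols <- c(cols, "qcov", "hcov")
  readr::write_tsv(hits[, cols], path, col_names = FALSE)
  invisible(path)
}
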