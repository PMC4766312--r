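#' Read a PAF alignment file into an alignment tibble
#'
#' Uses PAF columns 1 (query), 6 (target), 8/9 (target start/end,
#' 0-based half-open), 10 (matching bases) and 11 (alignment block
#' length); identity is `100 * matched_bases / aln_length`.
#'
#' @param path Path to a PAF file.
#' @return A tibble `read_id`, `target_id`, `tstart`, `tend`,
#'   `matched_bases`, `aln_length`, `pct_identity`.
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), target_id = character(),
      tstart = integer(), tend = integer(), matched_bases = integer(),
      aln_length = integer(), pct_identity = numeric()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    abort(paste0("malformed PAF row at line ", which(lengths(fields) < 12L)[1]))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  tibble::tibble(
    read_id = m[, 1], target_id = m[, 6],
    tstart = as.integer(m[, 8]), tend = as.integer(m[, 9]),
    matched_bases = as.integer(m[, 10]), aln_length = as.integer(m[, 11]),
    pct_identity = 100 * as.integer(m[, 10]) / as.integer(m[, 11])
  )
}

#' Read a text SAM file into an alignment tibble
#'
#' A minimal parser for plain-text SAM: header lines are skipped,
#' unmapped records (flag 0x4 or `*` reference) are dropped, and the
#' alignment length is taken from the CIGAR (M/I/D/=/X operations).
#' Matched bases are derived from the `NM` tag when present
#' (`aligned - NM`), else from `=`/`X` operations; records with neither
#' raise an error naming the read, since identity cannot be computed.
#'
#' @param path Path to a SAM file.
#' @return A tibble with the same columns as [read_paf()].
#' @export
read_sam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  rows <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) abort(paste0("malformed SAM record: ", substr(l, 1, 40)))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L || f[3] == "*") return(NULL)
    cig <- f[6]
    toks <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    lens <- as.integer(sub(".$", "", toks))
    kinds <- substring(toks, nchar(toks))
    aln_len <- sum(lens[kinds %in% c("M", "I", "D", "=", "X")])
    tlen <- sum(lens[kinds %in% c("M", "D", "=", "X")])
    indel <- sum(lens[kinds %in% c("I", "D")])
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(nm_tag) > 0L) {
      nm <- as.integer(sub("^NM:i:", "", nm_tag[1]))
      # NM counts mismatches plus inserted/deleted bases
      matched <- (aln_len - indel) - (nm - indel)
    } else if (any(kinds %in% c("=", "X"))) {
      matched <- sum(lens[kinds == "="])
    } else {
      abort(paste0("SAM record lacks NM tag and =/X CIGAR: cannot compute identity for read ", f[1]))
    }
    pos <- as.integer(f[4])
    tibble::tibble(
      read_id = f[1], target_id = f[3],
      tstart = pos - 1L, tend = pos - 1L + tlen,
      matched_bases = as.integer(matched), aln_length = as.integer(aln_len),
      pct_identity = 100 * matched / aln_len
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      read_id = character(), target_id = character(),
      tstart = integer(), tend = integer(), matched_bases = integer(),
      aln_length = integer(), pct_identity = numeric()
    )
  }
  out
}

#' Filter read alignments for recruitment
#'
#' The recruitment filter: an alignment recruits its read when it has at
#' least `min_identity` percent nucleotide identity over at least
#' `min_bases` aligned bases (both inclusive). Identity is matched
#' bases over alignment length including indels.
#'
#' @param alignments Alignment tibble ([read_paf()]/[read_sam()]).
#' @param min_identity Minimum percent identity (default 95).
#' @param min_bases Minimum alignment length in bases (default 50).
#' @return The subset of `alignments` passing the filter.
#' @export
filter_recruit <- function(alignments, min_identity = 95, min_bases = 50) {
  stopifnot(is.data.frame(alignments))
  need <- c("matched_bases", "aln_length")
  if (!all(need %in% names(alignments)) ||
    anyNA(alignments$matched_bases) || anyNA(alignments$aln_length)) {
    bad <- if (all(need %in% names(alignments))) {
      alignments$read_id[which(is.na(alignments$matched_bases) | is.na(alignments$aln_length))[1]]
    } else {
      "<all>"
    }
    abort(paste0("alignment lacking match counts: ", bad))
  }
  pid <- 100 * alignments$matched_bases / alignments$aln_length
  alignments[pid >= min_identity & alignments$aln_length >= min_bases, , drop = FALSE]
}

#' Reads Per Kilobase of genome per Gigabase of sample (RPKG)
#'
#' `rpkg = n_recruited / ((genome_length/1e3) * (sample_bases/1e9))`:
#' recruited-read counts normalised by target genome size (kb) and by
#' the size of the sampled metagenome (Gb of read bases), making
#' abundances comparable across genomes and datasets.
#'
#' @param n_recruited Recruited read count(s), `>= 0`.
#' @param genome_length Target genome length(s) in bases, `> 0`.
#' @param sample_bases Total bases in the (sub)sampled read set, `> 0`.
#' @return Numeric RPKG value(s).
#' @examples
#' compute_rpkg(6000, 1e6, 3e9) # 2.0
#' @export
compute_rpkg <- function(n_recruited, genome_length, sample_bases) {
  if (any(genome_length <= 0) || any(sample_bases <= 0)) {
    abort("genome_length and sample_bases must be positive")
  }
  if (any(n_recruited < 0)) abort("n_recruited must be >= 0")
  n_recruited / ((genome_length / 1e3) * (sample_bases / 1e9))
}

#' Categorise an RPKG value into presence/abundance bands
#'
#' Bands: `absent` below the presence cutoff (RPKG = 2), `low` in
#' `[2, 20)`, `moderate` in `[20, 120]`, `high` above 150. The interval
#' `(120, 150]` is left undefined by the banding convention; such
#' values are mapped to `moderate` and flagged.
#'
#' @param rpkg Non-negative RPKG value(s).
#' @param bounds Named list of band edges
#'   (`present = 2, low_hi = 20, mod_hi = 120, high = 150`).
#' @return A tibble `rpkg`, `category` (factor absent < low < moderate
#'   < high), `flagged_uncategorized` (logical: value fell in the
#'   undefined `(mod_hi, high]` gap).
#' @export
classify_abundance <- function(rpkg,
                               bounds = list(present = 2, low_hi = 20,
                                             mod_hi = 120, high = 150)) {
  if (any(rpkg < 0)) abort("rpkg must be >= 0")
  gap <- rpkg > bounds$mod_hi & rpkg <= bounds$high
  cat <- dplyr::case_when(
    rpkg < bounds$present ~ "absent",
    rpkg < bounds$low_hi ~ "low",
    rpkg <= bounds$mod_hi ~ "moderate",
    rpkg <= bounds$high ~ "moderate",
    TRUE ~ "high"
  )
  tibble::tibble(
    rpkg = rpkg,
    category = factor(cat, levels = c("absent", "low", "moderate", "high"), ordered = TRUE),
    flagged_uncategorized = gap
  )
}

#' Aggregate filtered alignments into per-target recruitment results
#'
#' Counts each read once per target (its best-identity alignment for
#' that target; reads aligning to several targets count for each) and
#' converts counts to RPKG with abundance categories.
#'
#' @param alignments Filtered alignment tibble ([filter_recruit()]).
#' @param genome_lengths Named numeric vector or two-column data frame
#'   (`target_id`, `length`) of target genome lengths in bases.
#' @param sample_bases Total bases of the sampled read set.
#' @param bounds Passed to [classify_abundance()].
#' @return A tibble with one row per target: `target_id`, `n_recruited`,
#'   `genome_length`, `sample_bases`, `rpkg`, `category`,
#'   `flagged_uncategorized`. Targets with no alignments report zero;
#'   alignments to targets missing from `genome_lengths` are dropped
#'   with a warning.
#' @export
recruit_sample <- function(alignments, genome_lengths, sample_bases,
                           bounds = list(present = 2, low_hi = 20,
                                         mod_hi = 120, high = 150)) {
  stopifnot(is.data.frame(alignments))
  if (is.data.frame(genome_lengths)) {
    genome_lengths <- setNames(as.numeric(genome_lengths[[2]]), genome_lengths[[1]])
  }
  unknown <- setdiff(unique(alignments$target_id), names(genome_lengths))
  if (length(unknown) > 0L) {
    warn(paste0("alignments to unknown target(s) dropped: ", paste(unknown, collapse = ", ")))
    alignments <- alignments[!alignments$target_id %in% unknown, , drop = FALSE]
  }
  counts <- alignments |>
    dplyr::arrange(.data$target_id, .data$read_id, dplyr::desc(.data$pct_identity)) |>
    dplyr::distinct(.data$target_id, .data$read_id) |>
    dplyr::count(.data$target_id, name = "n_recruited")
  out <- tibble::tibble(target_id = names(genome_lengths)) |>
    dplyr::left_join(counts, by = "target_id") |>
    dplyr::mutate(
      n_recruited = dplyr::coalesce(.data$n_recruited, 0L),
      genome_length = unname(genome_lengths[.data$target_id]),
      sample_bases = sample_bases,
      rpkg = compute_rpkg(.data$n_recruited, .data$genome_length, sample_bases)
    )
  cls <- classify_abundance(out$rpkg, bounds)
  out$category <- cls$category
  out$flagged_uncategorized <- cls$flagged_uncategorized
  out
}

#' RPKG bar chart of recruitment results
#'
#' @param results Tibble from [recruit_sample()].
#' @return A ggplot object; the dashed line marks the RPKG = 2 presence
#'   cutoff.
#' @export
plot_recruitment <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(
    x = stats::reorder(.data$target_id, -.data$rpkg),
    y = .data$rpkg, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "RPKG", title = "Read recruitment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
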