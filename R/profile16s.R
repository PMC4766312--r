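#' Select candidate 16S-bearing reads from hits against a curated database
#'
#' A read is a 16S candidate when its best hit against a small curated
#' 16S database passes all three thresholds: alignment length of at
#' least 90 bases, identity of at least 80%, e-value at most 1e-5. All
#' bounds are inclusive. The best hit per read is the highest bit score
#' (ties: highest identity, then lexicographically smallest subject id).
#'
#' @param hits Hit tibble as from [read_hits()].
#' @param min_aln Minimum alignment length in bases (default 90).
#' @param min_id Minimum percent identity (default 80).
#' @param max_evalue Maximum e-value (default 1e-5).
#' @return Character vector of candidate read ids (unique, sorted).
#' @export
select_candidate_reads <- function(hits, min_aln = 90, min_id = 80,
                                   max_evalue = 1e-5) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(character())
  best <- hits |>
    dplyr::arrange(
      .data$query_id, dplyr::desc(.data$bitscore),
      dplyr::desc(.data$pct_identity), .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  ok <- best$aln_length >= min_aln & best$pct_identity >= min_id &
    best$evalue <= max_evalue
  sort(best$query_id[ok])
}

#' Classify candidate reads by their best named reference hit
#'
#' Assigns each read the top-level taxon of its highest-scoring hit that
#' carries a taxon name ("best-named hit"): hits whose subjects have no
#' top-level name are skipped in rank order. Score is bit score when
#' present, otherwise percent identity; equal-score named hits are
#' broken by lexicographically smallest subject id and flagged.
#'
#' @param hits Hit tibble of candidate reads against a reference 16S
#'   database.
#' @param taxon_map Data frame mapping `subject_id` to `taxon`
#'   (first two columns used); subjects absent from the map, or mapped
#'   to `NA`/empty, are unnamed. The label `"chloroplast"` is an
#'   ordinary taxon here and is removed later by [build_profile()].
#' @param score `"bitscore"` (default) or `"identity"`.
#' @return A tibble `read_id`, `taxon`, `tie` (logical: assignment
#'   decided by tie-break), with `taxon = NA` for reads whose hits are
#'   all unnamed.
#' @export
classify_reads <- function(hits, taxon_map, score = c("bitscore", "identity")) {
  score <- match.arg(score)
  stopifnot(is.data.frame(hits), is.data.frame(taxon_map))
  tm <- tibble::tibble(
    subject_id = as.character(taxon_map[[1]]),
    taxon = as.character(taxon_map[[2]])
  )
  tm$taxon[!nzchar(tm$taxon %||% "")] <- NA_character_
  scored <- hits |>
    dplyr::left_join(tm, by = "subject_id") |>
    dplyr::mutate(.score = if (score == "bitscore") .data$bitscore else .data$pct_identity)
  named <- scored |>
    dplyr::filter(!is.na(.data$taxon)) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$.score), .data$subject_id) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      taxon = .data$taxon[1],
      tie = sum(.data$.score == .data$.score[1]) > 1L,
      .groups = "drop"
    )
  all_reads <- unique(hits$query_id)
  tibble::tibble(read_id = sort(all_reads)) |>
    dplyr::left_join(named, by = c(read_id = "query_id")) |>
    dplyr::mutate(tie = dplyr::coalesce(.data$tie, FALSE))
}

#' Build a top-level taxon profile from read classifications
#'
#' Chloroplast-labelled (or otherwise excluded) assignments are removed
#' first; fractions are then computed over the remaining assigned reads,
#' and taxa holding less than `min_fraction` of them are moved to the
#' excluded tier.
#'
#' @param assignments Tibble from [classify_reads()] (`read_id`,
#'   `taxon`).
#' @param min_fraction Minimum retained fraction of assigned reads
#'   (default 0.01, i.e. the 1% rule).
#' @param exclude_labels Taxon labels removed before fractions are
#'   computed (default `"chloroplast"`).
#' @return A `taxon_profile`: a tibble (`taxon`, `n_reads`, `fraction`,
#'   `status` in `retained`/`below_threshold`) with an `excluded`
#'   attribute counting reads removed per reason (one entry per excluded
#'   label, plus `unassigned`).
#' @export
build_profile <- function(assignments, min_fraction = 0.01,
                          exclude_labels = "chloroplast") {
  stopifnot(is.data.frame(assignments))
  excl <- c(
    setNames(
      vapply(exclude_labels, function(l) sum(assignments$taxon %in% l), 0L),
      exclude_labels
    ),
    unassigned = sum(is.na(assignments$taxon))
  )
  kept <- assignments |>
    dplyr::filter(!is.na(.data$taxon), !.data$taxon %in% exclude_labels)
  if (nrow(kept) == 0L) {
    warn("no assigned reads after exclusions: empty profile")
    out <- tibble::tibble(
      taxon = character(), n_reads = integer(),
      fraction = numeric(), status = character()
    )
    return(new_taxon_profile(out, excl, min_fraction))
  }
  out <- kept |>
    dplyr::count(.data$taxon, name = "n_reads") |>
    dplyr::mutate(
      fraction = .data$n_reads / sum(.data$n_reads),
      status = ifelse(.data$fraction >= min_fraction, "retained", "below_threshold")
    ) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
  new_taxon_profile(out, excl, min_fraction)
}

new_taxon_profile <- function(tbl, excluded, min_fraction) {
  structure(tbl,
    excluded = excluded, min_fraction = min_fraction,
    class = c("taxon_profile", class(tbl))
  )
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("<taxon_profile> ", sum(x$n_reads), " assigned reads, ",
    sum(x$status == "retained"), " retained taxa (min fraction ",
    attr(x, "min_fraction"), ")\n",
    sep = ""
  )
  excl <- attr(x, "excluded")
  if (sum(excl) > 0) {
    cat("excluded reads:", paste(names(excl), excl, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Bar chart of a taxon profile
#'
#' @param object A `taxon_profile` from [build_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot taxon_profile
#' @export
autoplot.taxon_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$taxon, -.data$fraction),
    y = 100 * .data$fraction, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of assigned 16S reads",
      title = "Top-level taxon profile"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
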