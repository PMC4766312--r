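#' Assign contigs to top-level taxa by per-gene best-hit voting
#'
#' Each predicted gene on a contig votes with the top-level taxon of its
#' best database hit (genes without a hit vote blank). A contig is
#' retained when it carries at least `min_genes` genes and not more than
#' half of its genes hit taxa different from the majority taxon.
#' "Not more than half" is inclusive by default: dissent equal to
#' exactly half the genes is allowed. Genes without hits count toward
#' the gene total but not toward dissent (they hit nothing), which is
#' also configurable. A tie for the modal taxon rejects the contig.
#'
#' @param votes Tibble with columns `gene_id`, `contig_id`, `taxon`
#'   (`NA` for genes without a hit).
#' @param min_genes Minimum genes per contig (default 3).
#' @param strict_half If `TRUE`, dissent must be strictly less than half
#'   (default `FALSE`: exactly half allowed).
#' @param hitless_in_denominator Count hitless genes in `n_genes` (and
#'   hence in the "half") (default `TRUE`); with `FALSE` they are
#'   ignored entirely.
#' @return A tibble with one row per contig: `contig_id`, `n_genes`,
#'   `majority_taxon`, `n_dissenting`, `retained`, `reason`.
#' @examples
#' votes <- tibble::tibble(
#'   gene_id = paste0("g", 1:4), contig_id = "c1",
#'   taxon = c("Euryarchaeota", "Euryarchaeota", "Bacteroidetes", "Proteobacteria")
#' )
#' assign_contig_taxa(votes)
#' @export
assign_contig_taxa <- function(votes, min_genes = 3L, strict_half = FALSE,
                               hitless_in_denominator = TRUE) {
  stopifnot(is.data.frame(votes))
  if (nrow(votes) == 0L) abort("empty vote table")
  stopifnot(all(c("gene_id", "contig_id", "taxon") %in% names(votes)))
  if (anyDuplicated(votes$gene_id)) {
    abort("a gene must belong to exactly one contig: duplicated gene_id")
  }
  votes |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_modify(~ vote_one_contig(
      .x$taxon, min_genes, strict_half, hitless_in_denominator
    )) |>
    dplyr::ungroup()
}

vote_one_contig <- function(taxa, min_genes, strict_half, hitless_in_denominator) {
  if (!hitless_in_denominator) taxa <- taxa[!is.na(taxa)]
  n <- length(taxa)
  hit <- taxa[!is.na(taxa)]
  res <- function(majority, dissent, retained, reason) {
    tibble::tibble(
      n_genes = n, majority_taxon = majority,
      n_dissenting = dissent, retained = retained, reason = reason
    )
  }
  if (n < min_genes) {
    lbl <- if (min_genes == 3L) "three" else min_genes
    return(res(NA_character_, NA_integer_, FALSE, paste0("fewer than ", lbl, " genes")))
  }
  if (length(hit) == 0L) {
    return(res(NA_character_, NA_integer_, FALSE, "no genes with hits"))
  }
  counts <- sort(table(hit), decreasing = TRUE)
  if (length(counts) > 1L && counts[1] == counts[2]) {
    return(res(NA_character_, NA_integer_, FALSE, "ambiguous majority"))
  }
  majority <- names(counts)[1]
  dissent <- sum(hit != majority)
  limit_ok <- if (strict_half) dissent < n / 2 else dissent <= n / 2
  if (!limit_ok) {
    return(res(majority, as.integer(dissent), FALSE, "more than half dissenting"))
  }
  res(majority, as.integer(dissent), TRUE, "ok")
}

#' Filter genome bins on contamination and concatenated length
#'
#' Retains bins whose external-QC contamination estimate is strictly
#' below `max_contamination` percent and whose concatenated contig
#' length reaches `min_length` bases. Bins without a contamination value
#' are excluded with reason `"no QC"`.
#'
#' @param bins Tibble with columns `bin_id`, `concatenated_length`
#'   (bases) and `contamination` (percent; `NA` when the QC report lacks
#'   the bin). Additional columns (e.g. `strain_heterogeneity`) are
#'   carried through untouched.
#' @param max_contamination Maximum contamination percent, exclusive
#'   (default 5).
#' @param min_length Minimum concatenated length in bases (default
#'   5e5, the lower end of the 0.5--0.8 Mb working range).
#' @return The input tibble with `retained` and `reason` columns added.
#' @export
filter_bins <- function(bins, max_contamination = 5, min_length = 5e5) {
  stopifnot(
    is.data.frame(bins),
    all(c("bin_id", "concatenated_length", "contamination") %in% names(bins))
  )
  bins |>
    dplyr::mutate(
      reason = dplyr::case_when(
        is.na(.data$contamination) ~ "no QC",
        .data$contamination >= max_contamination ~ "contamination",
        .data$concatenated_length < min_length ~ "too short",
        TRUE ~ "ok"
      ),
      retained = .data$reason == "ok"
    )
}
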