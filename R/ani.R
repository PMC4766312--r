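#' Cut a genome into consecutive fixed-length fragments
#'
#' Tiles each contig of a genome into non-overlapping consecutive
#' fragments of exactly `fragment_len` bases, the fragmentation step of
#' fragment-based ANI. The trailing remainder shorter than
#' `fragment_len` is dropped by default.
#'
#' @param genome A tibble (`id`, `seq`) as from [read_fasta()], or a
#'   single sequence string.
#' @param fragment_len Fragment length in bases (default 1020).
#' @param keep_remainder Keep the short terminal fragment of each contig
#'   (default `FALSE`).
#' @return A tibble `parent_id`, `index` (ordinal within parent),
#'   `start` (0-based inclusive), `end` (exclusive), `seq`.
#' @export
fragment_genome <- function(genome, fragment_len = 1020L, keep_remainder = FALSE) {
  if (is.character(genome)) {
    genome <- tibble::tibble(id = paste0("seq", seq_along(genome)), seq = genome)
  }
  stopifnot(is.data.frame(genome), fragment_len >= 1)
  frags <- purrr::map2_dfr(genome$id, genome$seq, function(id, s) {
    len <- nchar(s)
    n_full <- len %/% fragment_len
    starts <- seq_len(n_full) * fragment_len - fragment_len
    ends <- starts + fragment_len
    if (keep_remainder && len %% fragment_len > 0) {
      starts <- c(starts, n_full * fragment_len)
      ends <- c(ends, len)
    }
    if (length(starts) == 0L) {
      return(tibble::tibble(
        parent_id = character(), index = integer(),
        start = integer(), end = integer(), seq = character()
      ))
    }
    tibble::tibble(
      parent_id = id, index = seq_along(starts),
      start = as.integer(starts), end = as.integer(ends),
      seq = substring(s, starts + 1, ends)
    )
  })
  if (nrow(frags) == 0L) warn("genome shorter than fragment_len: zero fragments")
  frags
}

#' Built-in exact local aligner backend for [compute_ani()]
#'
#' Returns an aligner function that searches each query fragment against
#' every subject contig with exact Smith-Waterman local alignment
#' (via [Biostrings::pairwiseAlignment()]) and reports the best local
#' hit per fragment. Suitable for small instances; use
#' [ani_aligner_blast()] for genome-scale pairs.
#'
#' Identity is matched bases over alignment columns including gaps.
#'
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters
#'   (defaults 1, -1, 3, 1).
#' @return A function `(fragments, subject)` returning a tibble
#'   `query_id`, `pct_identity`, `aln_length`, `sstart`.
#' @export
ani_aligner_builtin <- function(match = 1, mismatch = -1,
                                gap_opening = 3, gap_extension = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)
  function(fragments, subject) {
    subj <- Biostrings::DNAStringSet(setNames(subject$seq, subject$id))
    purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
      q <- Biostrings::DNAString(fragments$seq[i])
      best <- NULL
      for (j in seq_along(subj)) {
        pa <- Biostrings::pairwiseAlignment(
          q, subj[[j]],
          type = "local", substitutionMatrix = mat,
          gapOpening = gap_opening, gapExtension = gap_extension
        )
        cand <- list(
          pid = Biostrings::pid(pa, type = "PID1"),
          len = Biostrings::nchar(pa),
          sstart = Biostrings::start(Biostrings::subject(pa))
        )
        if (is.null(best) || cand$pid * cand$len > best$pid * best$len ||
          (cand$pid * cand$len == best$pid * best$len && cand$sstart < best$sstart)) {
          best <- cand
        }
      }
      tibble::tibble(
        query_id = paste0(fragments$parent_id[i], ":", fragments$index[i]),
        pct_identity = best$pid, aln_length = best$len, sstart = best$sstart
      )
    })
  }
}

#' blastn aligner backend for [compute_ani()]
#'
#' Shells out to `makeblastdb`/`blastn` (which must be on `PATH`) with
#' unit match/mismatch scores, no dust filtering and a large final gap
#' X-dropoff so fragment alignments extend end to end, and parses the
#' 12-column tabular output. All hits are returned; [compute_ani()]
#' picks the best per fragment.
#'
#' @param evalue blastn e-value cutoff (default 1e-15, the fragment-ANI
#'   convention).
#' @param extra Extra command-line arguments appended to `blastn`.
#' @return A function `(fragments, subject)` returning a tibble
#'   `query_id`, `pct_identity`, `aln_length`, `sstart`.
#' @export
ani_aligner_blast <- function(evalue = 1e-15, extra = character()) {
  function(fragments, subject) {
    if (!nzchar(Sys.which("blastn"))) abort("blastn not found on PATH")
    td <- tempfile("anibl")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    qf <- file.path(td, "frags.fa")
    sf <- file.path(td, "subject.fa")
    write_fasta(
      tibble::tibble(
        id = paste0(fragments$parent_id, ":", fragments$index),
        seq = fragments$seq
      ),
      qf
    )
    write_fasta(subject, sf)
    db <- file.path(td, "db")
    out <- file.path(td, "hits.tsv")
    system2("makeblastdb", c("-in", sf, "-dbtype", "nucl", "-out", db),
      stdout = FALSE, stderr = FALSE
    )
    args <- c(
      "-task", "blastn", "-query", qf, "-db", db, "-outfmt", "6",
      "-evalue", format(evalue), "-reward", "1", "-penalty", "-1",
      "-gapopen", "5", "-gapextend", "2", "-xdrop_gap_final", "150",
      "-dust", "no", "-max_target_seqs", "10", "-out", out, extra
    )
    status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
    if (status != 0) abort("blastn failed")
    h <- read_hits(out, dialect = "standard")
    tibble::tibble(
      query_id = h$query_id, pct_identity = h$pct_identity,
      aln_length = h$aln_length, sstart = pmin(h$sstart, h$send)
    )
  }
}

resolve_aligner <- function(aligner) {
  if (is.function(aligner)) return(aligner)
  switch(match.arg(aligner, c("auto", "builtin", "blast")),
    builtin = ani_aligner_builtin(),
    blast = ani_aligner_blast(),
    auto = if (nzchar(Sys.which("blastn"))) ani_aligner_blast() else ani_aligner_builtin()
  )
}

#' Fragment-based average nucleotide identity and conserved DNA fraction
#'
#' Cuts each genome into consecutive 1020-bp fragments and searches them
#' against the other genome with a local aligner. Per direction, a
#' fragment is *used* when its best hit (highest identity x aligned
#' length, ties by first subject position) has at least
#' `min_frag_identity` percent identity over at least `min_frag_alncov`
#' of the fragment length; the direction's ANI is the mean identity of
#' used fragments. The conserved-DNA fraction is the total length of
#' fragments whose best hit reaches `conserved_min_identity` percent
#' identity, divided by the query genome length. Both directions and
#' their mean are reported; ANI of roughly 95--96% approximates the
#' species boundary and conserved DNA is its companion statistic.
#'
#' @param genome_a,genome_b Tibbles (`id`, `seq`) or single sequence
#'   strings; multi-contig genomes are fragmented per contig.
#' @param aligner `"auto"` (blastn when on PATH, else builtin),
#'   `"builtin"`, `"blast"`, or a backend function as returned by
#'   [ani_aligner_builtin()].
#' @param fragment_len Fragment length (default 1020 bases).
#' @param min_frag_identity Identity threshold for a fragment to enter
#'   the ANI mean (default 30 percent).
#' @param min_frag_alncov Minimum aligned fraction of the fragment
#'   (default 0.70).
#' @param conserved_min_identity Identity threshold for conserved DNA
#'   (default 90 percent).
#' @param mode `"both"` (reciprocal, default), `"ab"` or `"ba"`.
#' @param keep_remainder Passed to [fragment_genome()].
#' @return An `ani_result`: a one-row tibble with `ani_ab`, `ani_ba`,
#'   `ani_mean`, `conserved_fraction_ab`, `conserved_fraction_ba`,
#'   `n_fragments_used_ab`, `n_fragments_used_ba`. Undefined directions
#'   (no usable fragments) are `NA` and the mean falls back to the
#'   defined direction.
#' @export
compute_ani <- function(genome_a, genome_b, aligner = "auto",
                        fragment_len = 1020L, min_frag_identity = 30,
                        min_frag_alncov = 0.70, conserved_min_identity = 90,
                        mode = c("both", "ab", "ba"), keep_remainder = FALSE) {
  mode <- match.arg(mode)
  as_genome <- function(g, default_id) {
    if (is.character(g)) tibble::tibble(id = default_id, seq = g) else g
  }
  genome_a <- as_genome(genome_a, "A")
  genome_b <- as_genome(genome_b, "B")
  stopifnot(nrow(genome_a) > 0, nrow(genome_b) > 0)
  fn <- resolve_aligner(aligner)
  dir_stats <- function(query, subject) {
    frags <- fragment_genome(query, fragment_len, keep_remainder)
    if (nrow(frags) == 0L) {
      return(list(ani = NA_real_, cons = NA_real_, n_used = 0L))
    }
    hits <- fn(frags, subject)
    frag_ids <- paste0(frags$parent_id, ":", frags$index)
    best <- hits |>
      dplyr::mutate(.score = .data$pct_identity * .data$aln_length) |>
      dplyr::arrange(.data$query_id, dplyr::desc(.data$.score), .data$sstart) |>
      dplyr::distinct(.data$query_id, .keep_all = TRUE)
    best <- best[match(frag_ids, best$query_id), , drop = FALSE]
    frag_len_i <- frags$end - frags$start
    used <- !is.na(best$pct_identity) &
      best$pct_identity >= min_frag_identity &
      best$aln_length >= min_frag_alncov * frag_len_i
    conserved <- !is.na(best$pct_identity) &
      best$pct_identity >= conserved_min_identity
    list(
      ani = if (any(used)) mean(best$pct_identity[used]) else NA_real_,
      cons = sum(frag_len_i[conserved]) / sum(nchar(query$seq)),
      n_used = sum(used)
    )
  }
  ab <- if (mode %in% c("both", "ab")) dir_stats(genome_a, genome_b) else NULL
  ba <- if (mode %in% c("both", "ba")) dir_stats(genome_b, genome_a) else NULL
  ani_ab <- ab$ani %||% NA_real_
  ani_ba <- ba$ani %||% NA_real_
  if (is.na(ani_ab) && is.na(ani_ba)) warn("no usable fragments in either direction")
  ani_mean <- mean(c(ani_ab, ani_ba), na.rm = TRUE)
  if (is.nan(ani_mean)) ani_mean <- NA_real_
  out <- tibble::tibble(
    ani_ab = ani_ab, ani_ba = ani_ba, ani_mean = ani_mean,
    conserved_fraction_ab = ab$cons %||% NA_real_,
    conserved_fraction_ba = ba$cons %||% NA_real_,
    n_fragments_used_ab = ab$n_used %||% NA_integer_,
    n_fragments_used_ba = ba$n_used %||% NA_integer_
  )
  structure(out,
    params = list(
      fragment_len = fragment_len, min_frag_identity = min_frag_identity,
      min_frag_alncov = min_frag_alncov,
      conserved_min_identity = conserved_min_identity, mode = mode
    ),
    class = c("ani_result", class(out))
  )
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf(
    "<ani_result> ANI = %.2f%% (A->B %.2f, B->A %.2f); conserved DNA %.3f / %.3f\n",
    x$ani_mean, x$ani_ab, x$ani_ba,
    x$conserved_fraction_ab, x$conserved_fraction_ba
  ))
  invisible(x)
}

#' Tidy an ANI result into one row per direction
#'
#' @param x An `ani_result` from [compute_ani()].
#' @param ... Ignored.
#' @return A tibble `direction`, `ani`, `conserved_fraction`,
#'   `n_fragments_used`.
#' @method tidy ani_result
#' @export
tidy.ani_result <- function(x, ...) {
  tibble::tibble(
    direction = c("ab", "ba"),
    ani = c(x$ani_ab, x$ani_ba),
    conserved_fraction = c(x$conserved_fraction_ab, x$conserved_fraction_ba),
    n_fragments_used = c(x$n_fragments_used_ab, x$n_fragments_used_ba)
  )
}

#' One-row summary of an ANI result
#'
#' @param x An `ani_result` from [compute_ani()].
#' @param ... Ignored.
#' @return A one-row tibble `ani_mean`, `conserved_fraction_mean`,
#'   `fragment_len`.
#' @method glance ani_result
#' @export
glance.ani_result <- function(x, ...) {
  tibble::tibble(
    ani_mean = x$ani_mean,
    conserved_fraction_mean = mean(
      c(x$conserved_fraction_ab, x$conserved_fraction_ba),
      na.rm = TRUE
    ),
    fragment_len = attr(x, "params")$fragment_len
  )
}
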