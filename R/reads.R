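#' Subsample reads without replacement, keeping mates together
#'
#' Draws a reproducible without-replacement subsample of sequencing
#' reads. Read pairing is recognised either by the `/1`, `/2` (or `_1`,
#' `_2`) id-suffix convention or by declaring the file interleaved; a
#' pair is one sampling unit, so mates are kept or dropped together, and
#' `n` counts units (pairs where reads are paired, single reads
#' otherwise), matching the convention of subsampling "sequence pairs".
#'
#' @param reads A tibble of reads (`id`, `seq`, optionally `qual`).
#' @param n Number of units to draw; `n >=` the number of units returns
#'   everything.
#' @param seed Integer seed; the draw is bit-reproducible for a fixed
#'   seed.
#' @param pairing `"suffix"` (default: mate inferred from a trailing
#'   `/1`,`/2`,`_1`,`_2` on the id), `"interleaved"` (consecutive rows
#'   are mates) or `"none"` (every read its own unit).
#' @return A tibble of sampled reads in original order.
#' @export
subsample_reads <- function(reads, n, seed,
                            pairing = c("suffix", "interleaved", "none")) {
  pairing <- match.arg(pairing)
  stopifnot(is.data.frame(reads))
  if (length(n) != 1L || is.na(n) || n < 0) abort("n must be a single non-negative number")
  if (missing(seed) || is.null(seed)) abort("seed must be given")
  unit <- switch(pairing,
    none = seq_len(nrow(reads)),
    interleaved = (seq_len(nrow(reads)) + 1L) %/% 2L,
    suffix = {
      base <- sub("[/_][12]$", "", reads$id)
      match(base, unique(base))
    }
  )
  units <- unique(unit)
  k <- min(n, length(units))
  keep_units <- withr::with_seed(seed, sample(units, k))
  reads[unit %in% keep_units, , drop = FALSE]
}

#' GC content of nucleotide sequences
#'
#' Fraction (G+C)/(A+C+G+T) per sequence. Ambiguous bases (anything
#' outside ACGT, e.g. `N`) are excluded from the denominator by default,
#' as draft contigs contain gap characters.
#'
#' @param seq Character vector of nucleotide sequences (or a data frame
#'   with a `seq` column).
#' @param exclude_ambiguous Drop non-ACGT bases from the denominator
#'   (default `TRUE`); with `FALSE` they count in the denominator.
#' @return Numeric vector of fractions in `[0,1]`; a sequence with zero
#'   unambiguous bases yields `NA` with a warning.
#' @examples
#' gc_content(c("ATGC", "GGCC", "ANNG"))
#' @export
gc_content <- function(seq, exclude_ambiguous = TRUE) {
  if (is.data.frame(seq)) seq <- seq$seq
  stopifnot(is.character(seq))
  ss <- Biostrings::DNAStringSet(gsub("[^ACGTacgt]", "N", seq))
  f <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  denom <- if (exclude_ambiguous) rowSums(f) else nchar(seq)
  gc <- (f[, "G"] + f[, "C"]) / denom
  if (anyNA(gc) || any(is.nan(gc))) {
    warn("sequence(s) with zero unambiguous bases: GC undefined (NA)")
    gc[is.nan(gc)] <- NA_real_
  }
  unname(gc)
}
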