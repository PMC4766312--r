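#' Read a FASTA file into a tibble of sequence records
#'
#' Wraps [Biostrings::readBStringSet()] and returns one row per record
#' with the sequence uppercased. The first whitespace-delimited token of
#' each header is the record id.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @param kind `"nucleotide"` or `"protein"`; controls alphabet checking.
#' @return A tibble with columns `id`, `seq`, `kind` and a logical
#'   `has_ambiguous` flagging records containing residues outside the
#'   unambiguous alphabet (`N`s in nucleotide records, `X`/`B`/`Z`/... in
#'   proteins). Input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">A", "ACGT", ">B", "GGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble::tibble(
      id = character(), seq = character(),
      kind = character(), has_ambiguous = logical()
    ))
  }
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) abort("FASTA record with empty sequence")
  core <- if (kind == "nucleotide") "ACGT" else "ACDEFGHIKLMNPQRSTVWY"
  amb <- grepl(paste0("[^", core, "]"), seqs)
  tibble::tibble(id = ids, seq = unname(seqs), kind = kind, has_ambiguous = amb)
}

#' Write sequence records to FASTA
#'
#' @param records A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  ss <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a tibble of reads
#'
#' @param path Path to a (Sanger-quality) FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(as.character(ss)),
    qual = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

#' Write reads to FASTQ
#'
#' @param reads A data frame with columns `id`, `seq` and optionally
#'   `qual`; missing qualities are written as maximum Sanger quality.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else strrep("I", nchar(reads$seq))
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::PhredQuality(qual)
  qss <- Biostrings::QualityScaledDNAStringSet(ss, q)
  Biostrings::writeQualityScaledXStringSet(qss, path)
  invisible(path)
}
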