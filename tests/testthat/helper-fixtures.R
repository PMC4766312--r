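# Builders for small in-memory fixtures shared across tests.

# one hit-table row with sensible defaults
hit_row <- function(query_id = "r1", subject_id = "s1", pct_identity = 99,
                    aln_length = 100, evalue = 1e-10, bitscore = 200,
                    qcov = NA_real_, hcov = NA_real_) {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    pct_identity = pct_identity, aln_length = aln_length,
    mismatches = 0, gap_opens = 0, qstart = 1, qend = aln_length,
    sstart = 1, send = aln_length, evalue = evalue, bitscore = bitscore,
    qcov = qcov, hcov = hcov
  )
}

# an alignment record in read_paf() layout
aln_row <- function(read_id = "r1", target_id = "g1", matched_bases = 100,
                    aln_length = 100, tstart = 0) {
  tibble::tibble(
    read_id = read_id, target_id = target_id,
    tstart = tstart, tend = tstart + aln_length,
    matched_bases = matched_bases, aln_length = aln_length,
    pct_identity = 100 * matched_bases / aln_length
  )
}

# independent brute-force oracle for the contig retention rule
vote_rule_oracle <- function(taxa, min_genes = 3L) {
  n <- length(taxa)
  hit <- taxa[!is.na(taxa)]
  if (n < min_genes || length(hit) == 0L) {
    return(list(retained = FALSE, majority = NA_character_))
  }
  tab <- table(hit)
  top <- max(tab)
  modal <- names(tab)[tab == top]
  if (length(modal) > 1L) {
    return(list(retained = FALSE, majority = NA_character_))
  }
  dissent <- sum(hit != modal)
  list(retained = dissent <= n / 2, majority = modal, dissent = dissent)
}
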