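#' Generate a random genome sequence
#'
#' @param length Genome length in bases.
#' @param gc Target GC content in `[0,1]` (default 0.5).
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return A tibble (`id`, `seq`).
#' @export
random_genome <- function(length, gc = 0.5, seed, id = "genome1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- withr::with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p),
    collapse = ""
  ))
  tibble::tibble(id = id, seq = seq)
}

#' Mutate a genome at a controlled substitution divergence
#'
#' Substitutes each position independently with probability `divergence`
#' to a uniformly chosen different base, giving genome pairs of known
#' nucleotide divergence for ANI recovery experiments.
#'
#' @param genome Tibble (`id`, `seq`) or a single sequence string.
#' @param divergence Per-base substitution probability in `[0, 0.3]`.
#' @param seed Integer seed; output is identical for a fixed seed.
#' @return A list: `genome` (mutated tibble, ids suffixed `_mut`) and
#'   `manifest` (seed, divergence, genome length, realized substitution
#'   count and fraction).
#' @export
mutate_genome <- function(genome, divergence, seed) {
  if (is.character(genome)) genome <- tibble::tibble(id = "genome1", seq = genome)
  if (divergence < 0 || divergence > 0.3) {
    abort("divergence must be in [0, 0.3]")
  }
  bases <- c("A", "C", "G", "T")
  total_sub <- 0L
  mutated <- withr::with_seed(seed, {
    vapply(genome$seq, function(s) {
      v <- strsplit(s, "")[[1]]
      idx <- which(runif(length(v)) < divergence & v %in% bases)
      if (length(idx) > 0L) {
        v[idx] <- vapply(v[idx], function(b) sample(setdiff(bases, b), 1L), "")
      }
      total_sub <<- total_sub + length(idx)
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
  len <- sum(nchar(genome$seq))
  list(
    genome = tibble::tibble(id = paste0(genome$id, "_mut"), seq = mutated),
    manifest = list(
      seed = seed, divergence = divergence, genome_length = len,
      n_substitutions = total_sub, realized_divergence = total_sub / len
    )
  )
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Simulate shotgun reads from a community of known composition
#'
#' Draws reads (or read pairs) from a set of genomes with known relative
#' abundances and substitution error rate, and emits ground-truth
#' alignments alongside. Abundance is interpreted as relative coverage:
#' the expected read count of genome *i* is proportional to
#' `abundance[i] * length[i]`, so RPKG-style per-base abundance measures
#' recover the abundance ratios directly. Read start positions are
#' uniform along the genome; base errors are independent substitutions
#' at `error_rate` (no indels).
#'
#' @param genomes Tibble (`id`, `seq`) of community genomes.
#' @param abundances Numeric vector (same order as `genomes`) summing
#'   to 1.
#' @param n_reads Total number of reads (pairs count as two reads;
#'   rounded up to a full pair when `paired`).
#' @param read_len Read length in bases (default 150).
#' @param error_rate Per-base substitution error probability (default
#'   0.005).
#' @param paired Generate mate pairs from opposite fragment ends
#'   (default `TRUE`); mate ids carry `/1`, `/2` suffixes.
#' @param insert_mean,insert_sd Fragment (insert) size distribution for
#'   pairs (default 300 +/- 25, truncated to at least `read_len`).
#' @param seed Integer seed.
#' @return A list: `reads` (tibble `id`, `seq`), `truth` (alignment
#'   tibble in [read_paf()] layout: the error-free placement of every
#'   read) and `manifest` (parameters plus per-genome true read counts).
#' @export
simulate_reads <- function(genomes, abundances, n_reads, read_len = 150L,
                           error_rate = 0.005, paired = TRUE,
                           insert_mean = 300, insert_sd = 25, seed) {
  stopifnot(is.data.frame(genomes), nrow(genomes) > 0)
  if (n_reads <= 0) abort("n_reads must be positive")
  if (abs(sum(abundances) - 1) > 1e-6) abort("abundances must sum to 1")
  if (length(abundances) != nrow(genomes)) abort("one abundance per genome")
  lens <- nchar(genomes$seq)
  if (any(lens < read_len)) abort("every genome must be at least read_len long")
  w <- abundances * lens
  w <- w / sum(w)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    if (paired) {
      n_pairs <- ceiling(n_reads / 2)
      gi <- sample.int(nrow(genomes), n_pairs, replace = TRUE, prob = w)
      ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)), read_len), lens[gi])
      fstart <- floor(runif(n_pairs) * (lens[gi] - ins + 1)) + 1L
      s1 <- fstart
      s2 <- fstart + ins - read_len
      fwd <- substring(genomes$seq[gi], s1, s1 + read_len - 1L)
      rev <- revcomp(substring(genomes$seq[gi], s2, s2 + read_len - 1L))
      ids <- sprintf("r%06d", seq_len(n_pairs))
      reads <- tibble::tibble(
        id = c(rbind(paste0(ids, "/1"), paste0(ids, "/2"))),
        seq = c(rbind(fwd, rev))
      )
      truth_start <- c(rbind(s1, s2))
      truth_gi <- rep(gi, each = 2L)
    } else {
      gi <- sample.int(nrow(genomes), n_reads, replace = TRUE, prob = w)
      start <- floor(runif(n_reads) * (lens[gi] - read_len + 1)) + 1L
      reads <- tibble::tibble(
        id = sprintf("r%06d", seq_len(n_reads)),
        seq = substring(genomes$seq[gi], start, start + read_len - 1L)
      )
      truth_start <- start
      truth_gi <- gi
    }
    n_err <- integer(nrow(reads))
    if (error_rate > 0) {
      n_err <- rbinom(nrow(reads), read_len, error_rate)
      for (i in which(n_err > 0L)) {
        v <- strsplit(reads$seq[i], "")[[1]]
        pos <- sample.int(read_len, n_err[i])
        v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1L), "")
        reads$seq[i] <- paste(v, collapse = "")
      }
    }
    truth <- tibble::tibble(
      read_id = reads$id,
      target_id = genomes$id[truth_gi],
      tstart = truth_start - 1L,
      tend = truth_start - 1L + read_len,
      matched_bases = read_len - n_err,
      aln_length = as.integer(read_len),
      pct_identity = 100 * (read_len - n_err) / read_len
    )
    counts <- table(factor(genomes$id[truth_gi], levels = genomes$id))
    list(
      reads = reads, truth = truth,
      manifest = list(
        seed = seed, n_reads = nrow(reads), read_len = read_len,
        error_rate = error_rate, paired = paired,
        abundances = setNames(abundances, genomes$id),
        genome_lengths = setNames(lens, genomes$id),
        true_read_counts = setNames(as.integer(counts), names(counts)),
        sample_bases = nrow(reads) * read_len
      )
    )
  })
}

#' Write an alignment tibble as minimal PAF
#'
#' Emits the 12 mandatory PAF columns; query/strand/target-length
#' fields not represented in the tibble are filled with the alignment
#' length, `+`, and 0 respectively (readable back with [read_paf()]).
#'
#' @param alignments Alignment tibble ([read_paf()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path) {
  a <- alignments
  out <- paste(
    a$read_id, a$aln_length, 0L, a$aln_length, "+",
    a$target_id, 0L, a$tstart, a$tend,
    a$matched_bases, a$aln_length, 60L,
    sep = "\t"
  )
  writeLines(out, path)
  invisible(path)
}

#' Plant per-gene taxon votes with known retention outcomes
#'
#' Realises a vote-pattern specification exactly: each row of `pattern`
#' describes a class of contigs with a given gene count, majority-taxon
#' vote count, hitless gene count, and dissenting votes spread over the
#' other taxa (at most `n_majority - 1` per dissenting taxon, so the
#' planted majority stays strictly modal). The manifest records the
#' expected retention decision for every contig, computed directly from
#' the planted counts.
#'
#' @param pattern Data frame with columns `n_contigs`, `n_genes`,
#'   `n_majority` and optionally `n_hitless` (default 0); dissent is
#'   `n_genes - n_majority - n_hitless`.
#' @param taxa Character vector of available taxon labels.
#' @param seed Integer seed (shuffles which taxa play which role).
#' @param min_genes Retention rule parameter used for the expected
#'   decision (default 3).
#' @return A list: `votes` (tibble `gene_id`, `contig_id`, `taxon`) and
#'   `manifest` (tibble `contig_id`, `n_genes`, `majority_taxon`,
#'   `n_dissenting`, `n_hitless`, `expected_retained`).
#' @export
plant_contig_votes <- function(pattern, taxa, seed, min_genes = 3L) {
  stopifnot(is.data.frame(pattern), all(c("n_contigs", "n_genes", "n_majority") %in% names(pattern)))
  if (!"n_hitless" %in% names(pattern)) pattern$n_hitless <- 0L
  bad <- pattern$n_majority + pattern$n_hitless > pattern$n_genes
  if (any(bad)) abort("inconsistent pattern: n_majority + n_hitless > n_genes")
  withr::with_seed(seed, {
    contig_i <- 0L
    rows <- list()
    man <- list()
    for (k in seq_len(nrow(pattern))) {
      p <- pattern[k, ]
      dissent <- p$n_genes - p$n_majority - p$n_hitless
      if (dissent > 0 && length(taxa) < 2L) {
        abort("inconsistent pattern: dissent requires at least two taxa")
      }
      for (ci in seq_len(p$n_contigs)) {
        contig_i <- contig_i + 1L
        cid <- sprintf("contig%04d", contig_i)
        maj <- sample(taxa, 1L)
        others <- setdiff(taxa, maj)
        per_cap <- max(p$n_majority - 1L, 0L)
        if (dissent > length(others) * per_cap) {
          abort("inconsistent pattern: cannot spread dissent without a modal tie")
        }
        dt <- character(0)
        if (dissent > 0) {
          pool <- rep(sample(others), length.out = length(others) * per_cap)
          dt <- pool[seq_len(dissent)]
        }
        votes <- c(
          rep(maj, p$n_majority), dt, rep(NA_character_, p$n_hitless)
        )
        votes <- sample(votes)
        rows[[contig_i]] <- tibble::tibble(
          gene_id = sprintf("%s_g%03d", cid, seq_along(votes)),
          contig_id = cid, taxon = votes
        )
        man[[contig_i]] <- tibble::tibble(
          contig_id = cid, n_genes = p$n_genes,
          majority_taxon = if (p$n_majority > 0) maj else NA_character_,
          n_dissenting = dissent, n_hitless = p$n_hitless,
          expected_retained = p$n_genes >= min_genes &&
            p$n_majority > 0 && dissent <= p$n_genes / 2
        )
      }
    }
    list(votes = dplyr::bind_rows(rows), manifest = dplyr::bind_rows(man))
  })
}

#' Plant a marker hit table with known completeness tiers
#'
#' Exactly `k_loose` markers receive a hit passing the e-value cutoff,
#' of which exactly `k_strict` also pass both coverage thresholds; the
#' remaining loose-only markers get a hit failing one coverage.
#' Distractor hits above the e-value cutoff are added for markers
#' outside the loose set.
#'
#' @param markers A [marker_set()].
#' @param k_strict,k_loose Planted tier sizes, `k_strict <= k_loose <=`
#'   set size.
#' @param seed Integer seed.
#' @param max_evalue E-value cutoff the table is planted against
#'   (default 1e-5).
#' @param n_distractors Number of above-cutoff distractor hits (default
#'   5, capped at the number of absent markers).
#' @return A list: `hits` (tibble `marker_id`, `gene_id`, `evalue`,
#'   `hcov`, `qcov`) and `manifest` (`strict_ids`, `loose_ids`,
#'   expected lower/upper completeness percentages).
#' @export
plant_marker_hits <- function(markers, k_strict, k_loose, seed,
                              max_evalue = 1e-5, n_distractors = 5L) {
  stopifnot(inherits(markers, "marker_set"))
  if (k_strict > k_loose || k_loose > markers$size || k_strict < 0) {
    abort("need 0 <= k_strict <= k_loose <= marker set size")
  }
  withr::with_seed(seed, {
    loose_ids <- sample(markers$markers, k_loose)
    strict_ids <- if (k_strict > 0) sample(loose_ids, k_strict) else character()
    loose_only <- setdiff(loose_ids, strict_ids)
    absent <- setdiff(markers$markers, loose_ids)
    mk <- function(ids, ev_lo, ev_hi, hcov, qcov) {
      if (length(ids) == 0L) return(NULL)
      tibble::tibble(
        marker_id = ids,
        gene_id = sprintf("gene_%s", ids),
        evalue = 10^runif(length(ids), log10(ev_lo), log10(ev_hi)),
        hcov = hcov, qcov = qcov
      )
    }
    hits <- dplyr::bind_rows(
      mk(strict_ids, 1e-30, max_evalue,
         runif(length(strict_ids), 0.85, 0.99), runif(length(strict_ids), 0.85, 0.99)),
      mk(loose_only, 1e-30, max_evalue,
         runif(length(loose_only), 0.2, 0.6), runif(length(loose_only), 0.85, 0.99)),
      mk(head(sample(absent), n_distractors), max_evalue * 1e2, 1e-1, 0.9, 0.9)
    )
    hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
    list(
      hits = hits,
      manifest = list(
        seed = seed, strict_ids = sort(strict_ids), loose_ids = sort(loose_ids),
        expected_lower_pct = 100 * k_strict / markers$size,
        expected_upper_pct = 100 * k_loose / markers$size
      )
    )
  })
}

#' Simulate a proteome with a controlled modal pI
#'
#' Builds protein sequences whose residue compositions are solved
#' against the package's own pI solver: for each protein a target pI is
#' drawn around `target_mode_pI`, the acid/base share of its charged
#' residues is found by bisection on the composition pI, and the
#' integer composition is locally refined to the closest achievable pI.
#' Charged residues are D/E (acid) and K/R/H (base); the neutral
#' backbone is drawn from G, A, S, T, V, L.
#'
#' @param n_proteins Number of proteins.
#' @param target_mode_pI Desired modal pI, in (2, 12).
#' @param spread Standard deviation of per-protein target pIs (default
#'   0.15; the histogram mode then sits within one bin or so of the
#'   target).
#' @param min_len,max_len Protein length range (default 60--300).
#' @param charged_fraction Fraction of residues that are charged
#'   (default 0.4).
#' @param pka_table pKa table the construction is calibrated against.
#' @param seed Integer seed.
#' @return A list: `proteome` (tibble `id`, `seq`) and `manifest`
#'   (tibble `id`, `length`, `target_pi`, `achieved_pi`, plus
#'   parameters as attributes).
#' @export
simulate_proteome <- function(n_proteins, target_mode_pI, spread = 0.15,
                              min_len = 60L, max_len = 300L,
                              charged_fraction = 0.4,
                              pka_table = pka_table_default(), seed) {
  if (target_mode_pI <= 2 || target_mode_pI >= 12) {
    abort("target_mode_pI must be in (2, 12)")
  }
  stopifnot(min_len >= 30L, max_len >= min_len, n_proteins >= 1)
  neutral <- c("G", "A", "S", "T", "V", "L")
  # fixed His/Tyr buffer so composition pI moves smoothly with the
  # acid share; His-rich when the target sits in the 6.5-8.5 titration
  # gap, where charge is otherwise flat and achievable pIs sparse
  h_frac <- if (target_mode_pI > 5.5 && target_mode_pI < 8.5) 0.15 else 0.03
  n_buf <- function(m) c(H = round(h_frac * m), Y = round(0.03 * m))
  comp_counts <- function(m, c_charged, a_share) {
    buf <- n_buf(m)
    n_acid <- round(a_share * c_charged)
    n_base <- c_charged - n_acid
    acids <- c(D = n_acid %/% 2 + n_acid %% 2, E = n_acid %/% 2)
    bases <- c(K = n_base %/% 2 + n_base %% 2, R = n_base %/% 2)
    # counts vector aligned with pka_table_default row order
    c(
      1, acids[["D"]], acids[["E"]], buf[["H"]], 0, 1, buf[["Y"]],
      bases[["K"]], bases[["R"]]
    )
  }
  pi_of <- function(m, c_charged, a_share) {
    bisect_pi(comp_counts(m, c_charged, a_share), pka_table)
  }
  withr::with_seed(seed, {
    lens <- sample(seq(min_len, max_len), n_proteins, replace = TRUE)
    targets <- pmin(pmax(rnorm(n_proteins, target_mode_pI, spread), 2.6), 11.9)
    seqs <- character(n_proteins)
    achieved <- numeric(n_proteins)
    for (i in seq_len(n_proteins)) {
      m <- lens[i]
      buf <- n_buf(m)
      cc <- round(charged_fraction * m) - sum(buf)
      lo <- 0
      hi <- 1
      # composition pI is decreasing in the acid share
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (pi_of(m, cc, mid) > targets[i]) lo <- mid else hi <- mid
      }
      n_acid0 <- round(((lo + hi) / 2) * cc)
      cand <- unique(pmin(pmax(n_acid0 + (-3:3), 0L), cc))
      pis <- vapply(cand, function(na) pi_of(m, cc, na / cc), 0)
      best <- which.min(abs(pis - targets[i]))
      n_acid <- cand[best]
      achieved[i] <- pis[best]
      n_base <- cc - n_acid
      acids <- c(rep("D", n_acid %/% 2 + n_acid %% 2), rep("E", n_acid %/% 2))
      bases <- c(rep("K", n_base %/% 2 + n_base %% 2), rep("R", n_base %/% 2))
      buffer <- c(rep("H", buf[["H"]]), rep("Y", buf[["Y"]]))
      backbone <- sample(neutral, m - cc - sum(buf), replace = TRUE)
      seqs[i] <- paste(sample(c(acids, bases, buffer, backbone)), collapse = "")
    }
    manifest <- tibble::tibble(
      id = sprintf("prot%05d", seq_len(n_proteins)),
      length = lens, target_pi = targets, achieved_pi = achieved
    )
    attr(manifest, "params") <- list(
      seed = seed, target_mode_pI = target_mode_pI, spread = spread,
      charged_fraction = charged_fraction
    )
    list(
      proteome = tibble::tibble(id = manifest$id, seq = seqs),
      manifest = manifest
    )
  })
}
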