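test_that("FASTA round-trip preserves ids, sequences and order", {
  recs <- dplyr::bind_rows(
    random_genome(137, seed = 1, id = "A"),
    random_genome(211, seed = 2, id = "B"),
    random_genome(64, seed = 3, id = "C")
  )
  fa <- withr::local_tempfile(fileext = ".fna")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, c("A", "B", "C"))
  expect_equal(back$seq, recs$seq)
  expect_equal(nchar(back$seq), c(137, 211, 64))
  expect_false(any(back$has_ambiguous))
})

test_that("FASTA reader flags problems", {
  fa <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">A", "ACGT", ">A", "GGTT"), fa)
  expect_error(read_fasta(fa), "duplicate.*A")
  writeLines(character(), fa)
  expect_warning(out <- read_fasta(fa), "empty")
  expect_equal(nrow(out), 0L)
  writeLines(c(">N1", "ACGTN"), fa)
  expect_true(read_fasta(fa)$has_ambiguous)
})

test_that("FASTQ round-trip preserves reads and qualities", {
  reads <- tibble::tibble(
    id = c("r1/1", "r1/2"), seq = c("ACGTACGT", "TTGGCCAA"),
    qual = c("IIIIHHHH", "AAAAFFFF")
  )
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)
})

test_that("hit tables parse both dialects and compute coverages", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("read1\tdb7\t80.0\t95\t19\t0\t1\t95\t5\t99\t1e-5\t120", tsv)
  h <- read_hits(tsv)
  expect_equal(h$pct_identity, 80.0)
  expect_equal(h$evalue, 1e-5)
  expect_true(is.na(h$qcov))
  # coverages derivable from supplied lengths: span 95 of a 100-base read
  h2 <- read_hits(tsv, query_lengths = c(read1 = 100), subject_lengths = c(db7 = 190))
  expect_equal(h2$qcov, 0.95)
  expect_equal(h2$hcov, 0.5)
  writeLines("read1\tdb7\t90\t100\t10\t0\t1\t100\t1\t100\t1e-9\t150\t0.85\t0.91", tsv)
  h3 <- read_hits(tsv)
  expect_equal(h3$qcov, 0.85)
  expect_equal(h3$hcov, 0.91)
})

test_that("malformed hit rows raise errors naming the line", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "r1\ts1\t99\t100\t1\t0\t1\t100\t1\t100\t1e-9\t180",
    "r2\ts1\tbroken"
  ), tsv)
  expect_error(read_hits(tsv), "line 2")
})

test_that("round-trip through write_hits is lossless", {
  h <- dplyr::bind_rows(
    hit_row("r1", "s1", 97.5, evalue = 3e-8),
    hit_row("r2", "s2", 80, aln_length = 90, qcov = 0.9, hcov = 0.8)
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(h, tsv, extended = TRUE)
  expect_equal(read_hits(tsv), h)
})

test_that("subsampling is exact, reproducible, and keeps mates together", {
  ids <- c(rbind(paste0("p", 1:50, "/1"), paste0("p", 1:50, "/2")))
  reads <- tibble::tibble(id = ids, seq = strrep("A", 10))
  s1 <- subsample_reads(reads, 20, seed = 42)
  s2 <- subsample_reads(reads, 20, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 40L) # 20 pairs = 40 reads
  base <- sub("/[12]$", "", s1$id)
  expect_true(all(table(base) == 2L))
  # saturation
  expect_equal(nrow(subsample_reads(reads, 1000, seed = 1)), 100L)
  expect_error(subsample_reads(reads, -1, seed = 1), "non-negative")
  expect_error(subsample_reads(reads, 5), "seed")
})

test_that("per-read inclusion frequency matches the binomial expectation", {
  reads <- tibble::tibble(id = paste0("r", 1:40), seq = strrep("A", 5))
  incl <- rowSums(vapply(
    1:10,
    function(s) reads$id %in% subsample_reads(reads, 20, seed = s, pairing = "none")$id,
    logical(40)
  ))
  # inclusion probability 0.5 over 10 draws; allow 4 binomial SDs
  expect_true(all(abs(incl / 10 - 0.5) <= 4 * sqrt(0.25 / 10)))
})

test_that("gc_content matches a brute-force count and handles ambiguity", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  seqs <- withr::with_seed(9, vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
  }, ""))
  brute <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    sum(v %in% c("G", "C")) / sum(v %in% c("A", "C", "G", "T"))
  }, 0, USE.NAMES = FALSE)
  expect_equal(gc_content(seqs), brute)
  expect_warning(na_gc <- gc_content("NNNN"), "undefined")
  expect_true(is.na(na_gc))
  expect_equal(gc_content("ANNG", exclude_ambiguous = FALSE), 0.25)
})
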