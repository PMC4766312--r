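test_that("the 95% / 50 bp recruitment filter is inclusive at the boundary", {
  alns <- dplyr::bind_rows(
    aln_row("below_id", matched_bases = 949, aln_length = 1000),   # 94.9%
    aln_row("short", matched_bases = 49, aln_length = 49),         # 100% but 49 bp
    aln_row("edge", matched_bases = 95, aln_length = 100),         # 95.0%, 100 bp
    aln_row("edge_len", matched_bases = 50, aln_length = 50)       # 100%, 50 bp
  )
  kept <- filter_recruit(alns)
  expect_equal(kept$read_id, c("edge", "edge_len"))
  broken <- alns
  broken$matched_bases[2] <- NA
  expect_error(filter_recruit(broken), "short")
})

test_that("RPKG formula is exact and scale-invariant", {
  expect_equal(compute_rpkg(6000, 1e6, 3e9), 2.0)
  expect_equal(compute_rpkg(0, 1e6, 3e9), 0)
  expect_equal(compute_rpkg(12000, 1e6, 6e9), compute_rpkg(6000, 1e6, 3e9))
  # linear in counts, inverse in genome and sample size
  expect_equal(compute_rpkg(100, 2e6, 1e9), compute_rpkg(200, 2e6, 1e9) / 2)
  expect_equal(compute_rpkg(100, 2e6, 1e9), compute_rpkg(100, 1e6, 1e9) / 2)
  expect_error(compute_rpkg(10, 0, 1e9), "positive")
  expect_error(compute_rpkg(-1, 1e6, 1e9), ">= 0")
})

test_that("abundance bands follow the presence and band cutoffs", {
  out <- classify_abundance(c(1.9, 2, 19.9, 20, 60, 120, 130, 150, 151, 200))
  expect_equal(
    as.character(out$category),
    c("absent", "low", "low", "moderate", "moderate", "moderate",
      "moderate", "moderate", "high", "high")
  )
  expect_equal(out$flagged_uncategorized,
               c(F, F, F, F, F, F, T, T, F, F))
  expect_error(classify_abundance(-0.1), ">= 0")
})

test_that("recruitment counts each read once per target", {
  alns <- dplyr::bind_rows(
    aln_row("r1", "g1", 100, 100),
    aln_row("r1", "g1", 98, 100, tstart = 500), # same read, same target
    aln_row("r1", "g2", 99, 100),               # same read, other target
    aln_row("r2", "g1", 97, 100)
  )
  res <- recruit_sample(alns, c(g1 = 1e6, g2 = 1e6), 1e9)
  expect_equal(res$n_recruited[res$target_id == "g1"], 2L)
  expect_equal(res$n_recruited[res$target_id == "g2"], 1L)
  # brute-force dedup oracle
  brute <- length(unique(alns$read_id[alns$target_id == "g1"]))
  expect_equal(res$n_recruited[res$target_id == "g1"], brute)
  expect_warning(
    recruit_sample(aln_row("r1", "ghost"), c(g1 = 1e6), 1e9),
    "unknown target"
  )
})

test_that("PAF round-trips through write_paf/read_paf", {
  alns <- dplyr::bind_rows(
    aln_row("r1", "g1", 142, 150, tstart = 10),
    aln_row("r2", "g2", 150, 150, tstart = 0)
  )
  paf <- withr::local_tempfile(fileext = ".paf")
  write_paf(alns, paf)
  expect_equal(read_paf(paf), alns)
})

test_that("the SAM parser derives identity from NM or =/X CIGARs", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:g1\tLN:10000",
    # 150M with 3 mismatches
    "r1\t0\tg1\t101\t60\t150M\t*\t0\t0\tACGT\tIIII\tNM:i:3",
    # 70M 2I 78M with NM 5 (2 inserted + 3 mismatches): 148 matched / 150 cols
    "r2\t16\tg1\t201\t60\t70M2I78M\t*\t0\t0\tACGT\tIIII\tNM:i:5",
    # =/X dialect without NM
    "r3\t0\tg1\t301\t60\t140=10X\t*\t0\t0\tACGT\tIIII",
    # unmapped: skipped
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII"
  ), sam)
  out <- read_sam(sam)
  expect_equal(out$read_id, c("r1", "r2", "r3"))
  expect_equal(out$matched_bases, c(147L, 145L, 140L))
  expect_equal(out$aln_length, c(150L, 150L, 150L))
  expect_equal(out$tstart, c(100L, 200L, 300L))
  # plain M CIGAR without NM cannot yield identity
  writeLines(c("r9\t0\tg1\t1\t60\t150M\t*\t0\t0\tA\tI"), sam)
  expect_error(read_sam(sam), "r9")
})

test_that("a 10:3:1 community recovers its RPKG ratios", {
  genomes <- dplyr::bind_rows(
    random_genome(30000, seed = 61, id = "gHigh"),
    random_genome(30000, seed = 62, id = "gMid"),
    random_genome(30000, seed = 63, id = "gLow")
  )
  ab <- c(10, 3, 1) / 14
  sim <- simulate_reads(genomes, ab, 30000, seed = 64, paired = FALSE)
  res <- sim$truth |>
    filter_recruit() |>
    recruit_sample(setNames(nchar(genomes$seq), genomes$id), sim$manifest$sample_bases)
  rpkg <- setNames(res$rpkg, res$target_id)
  expect_lt(abs(rpkg[["gHigh"]] / rpkg[["gMid"]] - 10 / 3) / (10 / 3), 0.1)
  expect_lt(abs(rpkg[["gMid"]] / rpkg[["gLow"]] - 3) / 3, 0.1)
})
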