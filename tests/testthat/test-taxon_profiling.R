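test_that("candidate selection applies all three inclusive thresholds", {
  hits <- dplyr::bind_rows(
    hit_row("short", aln_length = 89, pct_identity = 95, evalue = 1e-10),
    hit_row("edge", aln_length = 90, pct_identity = 80, evalue = 1e-5),
    hit_row("weak_id", aln_length = 120, pct_identity = 79.9, evalue = 1e-10),
    hit_row("weak_e", aln_length = 120, pct_identity = 95, evalue = 2e-5),
    hit_row("good", aln_length = 150, pct_identity = 92, evalue = 1e-20)
  )
  expect_equal(select_candidate_reads(hits), c("edge", "good"))
  expect_equal(select_candidate_reads(hits[0, ]), character())
})

test_that("planted passing reads are recovered exactly", {
  pass <- paste0("p", 1:40)
  fail <- paste0("f", 1:60)
  hits <- dplyr::bind_rows(
    purrr::map_dfr(pass, ~ hit_row(.x, aln_length = 120, pct_identity = 90, evalue = 1e-12)),
    purrr::map_dfr(fail, ~ hit_row(.x, aln_length = 70, pct_identity = 90, evalue = 1e-12))
  )
  expect_equal(select_candidate_reads(hits), sort(pass))
})

test_that("classification follows the best *named* hit", {
  tm <- tibble::tibble(subject_id = c("n1", "n2", "chl1"),
                       taxon = c("Euryarchaeota", "Bacteroidetes", "chloroplast"))
  hits <- dplyr::bind_rows(
    hit_row("r1", "unnamed9", bitscore = 300),  # best hit carries no name
    hit_row("r1", "n1", bitscore = 250),
    hit_row("r2", "n2", bitscore = 100),
    hit_row("r3", "unnamed9", bitscore = 90)
  )
  out <- classify_reads(hits, tm)
  expect_equal(out$taxon[out$read_id == "r1"], "Euryarchaeota")
  expect_equal(out$taxon[out$read_id == "r2"], "Bacteroidetes")
  expect_true(is.na(out$taxon[out$read_id == "r3"]))
})

test_that("equal-score ties break lexicographically and survive permutation", {
  tm <- tibble::tibble(subject_id = c("zeta", "alpha"),
                       taxon = c("Proteobacteria", "Euryarchaeota"))
  hits <- dplyr::bind_rows(
    hit_row("r1", "zeta", bitscore = 200),
    hit_row("r1", "alpha", bitscore = 200)
  )
  for (perm in list(1:2, 2:1)) {
    out <- classify_reads(hits[perm, ], tm)
    expect_equal(out$taxon, "Euryarchaeota")
    expect_true(out$tie)
  }
})

test_that("profile applies the chloroplast filter before the 1% rule", {
  assignments <- tibble::tibble(
    read_id = paste0("r", 1:1100),
    taxon = c(
      rep("Euryarchaeota", 700), rep("Bacteroidetes", 292),
      rep("Rare", 8), rep("chloroplast", 100)
    )
  )
  prof <- build_profile(assignments)
  tbl <- tibble::as_tibble(prof)
  # fractions over the 1000 post-chloroplast assigned reads
  expect_equal(tbl$fraction[tbl$taxon == "Euryarchaeota"], 0.7)
  expect_equal(tbl$status[tbl$taxon == "Rare"], "below_threshold")
  expect_equal(unname(attr(prof, "excluded")["chloroplast"]), 100L)
  expect_true(sum(tbl$fraction[tbl$status == "retained"]) <= 1)
  # adding the excluded taxon's fraction back restores the total
  expect_equal(sum(tbl$fraction), 1)
})

test_that("degenerate profiles behave", {
  one <- build_profile(tibble::tibble(read_id = "r1", taxon = "X"))
  expect_equal(one$fraction, 1.0)
  expect_warning(
    empty <- build_profile(tibble::tibble(read_id = "r1", taxon = NA_character_)),
    "empty profile"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("a planted 60/30/10 community is recovered within half a point", {
  probs <- c(Euryarchaeota = 0.6, Bacteroidetes = 0.3, Proteobacteria = 0.1)
  taxa <- withr::with_seed(7, sample(names(probs), 10000, TRUE, probs))
  prof <- build_profile(tibble::tibble(read_id = paste0("r", 1:10000), taxon = taxa))
  got <- setNames(prof$fraction, prof$taxon)[names(probs)]
  expect_true(all(abs(got - probs) <= 0.005))
})

test_that("profile recovery error shrinks with read depth", {
  probs <- c(A = 0.6, B = 0.3, C = 0.1)
  err_at <- function(n, seed) {
    taxa <- withr::with_seed(seed, sample(names(probs), n, TRUE, probs))
    prof <- build_profile(tibble::tibble(read_id = seq_len(n), taxon = taxa))
    max(abs(setNames(prof$fraction, prof$taxon)[names(probs)] - probs))
  }
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    mean(vapply(1:5, function(s) err_at(n, s), 0))
  }, 0)
  expect_true(errs[3] < errs[1])
})
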