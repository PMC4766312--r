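test_that("fragmentation tiles contigs and drops remainders", {
  g <- random_genome(10200, seed = 1)
  expect_equal(nrow(fragment_genome(g)), 10L)
  g2 <- random_genome(10500, seed = 2)
  f2 <- fragment_genome(g2)
  expect_equal(nrow(f2), 10L)
  expect_equal(max(f2$end), 10200L)
  expect_equal(nrow(fragment_genome(g2, keep_remainder = TRUE)), 11L)
  # multi-contig arithmetic: 2040 + 3060 + 1000 -> 2 + 3 + 0
  multi <- dplyr::bind_rows(
    random_genome(2040, seed = 3, id = "c1"),
    random_genome(3060, seed = 4, id = "c2"),
    random_genome(1000, seed = 5, id = "c3")
  )
  fm <- fragment_genome(multi)
  expect_equal(nrow(fm), 5L)
  expect_equal(as.vector(table(fm$parent_id)[c("c1", "c2")]), c(2L, 3L))
  # fragments tile the parent without overlap
  c2 <- fm[fm$parent_id == "c2", ]
  expect_equal(c2$start, c(0L, 1020L, 2040L))
  expect_equal(c2$end - c2$start, rep(1020L, 3))
  expect_warning(fragment_genome(random_genome(500, seed = 6)), "zero fragments")
})

test_that("a genome against itself gives ANI 100 exactly (builtin aligner)", {
  g <- random_genome(5100, seed = 10, id = "self")
  r <- compute_ani(g, g, aligner = "builtin")
  expect_equal(r$ani_mean, 100)
  expect_equal(r$ani_ab, 100)
  expect_equal(r$n_fragments_used_ab, 5L)
  # conserved DNA covers all full fragments: 5*1020/5100
  expect_equal(r$conserved_fraction_ab, 1.0)
})

test_that("builtin aligner recovers a planted 2% divergence", {
  g <- random_genome(8160, seed = 20, id = "anc")
  mut <- mutate_genome(g, 0.02, seed = 21)
  r <- compute_ani(g, mut$genome, aligner = "builtin")
  expect_gte(r$ani_mean, 97.5)
  expect_lte(r$ani_mean, 98.5)
  # reciprocal directions agree without rearrangement
  expect_lt(abs(r$ani_ab - r$ani_ba), 1)
  expect_equal(r$conserved_fraction_ab, 1.0)
})

test_that("fragment usage and conserved-DNA thresholds act on best hits", {
  # pluggable backend contract: inject crafted best hits
  fake <- function(hits) function(fragments, subject) hits
  g <- random_genome(3060, seed = 30, id = "g") # fragments g:1..g:3
  crafted <- tibble::tibble(
    query_id = c("g:1", "g:2", "g:3"),
    pct_identity = c(95, 25, 92),        # g:2 fails the 30% identity floor
    aln_length = c(1020, 1020, 500),     # g:3 fails 70% coverage
    sstart = 1
  )
  r <- compute_ani(g, g, aligner = fake(crafted), mode = "ab")
  expect_equal(r$n_fragments_used_ab, 1L)
  expect_equal(r$ani_ab, 95)
  # conserved DNA counts identity >= 90 regardless of the usage filter
  expect_equal(r$conserved_fraction_ab, 2 * 1020 / 3060)
  # no hit reaches 90% identity -> conserved fraction 0
  crafted$pct_identity <- c(80, 25, 60)
  r2 <- compute_ani(g, g, aligner = fake(crafted), mode = "ab")
  expect_equal(r2$conserved_fraction_ab, 0)
  # best hit per fragment is by identity x length, ties by subject position
  dup <- tibble::tibble(
    query_id = c("g:1", "g:1", "g:2", "g:3"),
    pct_identity = c(90, 96, 95, 95),
    aln_length = c(1020, 900, 1020, 1020),
    sstart = c(1, 5, 1, 1)
  )
  r3 <- compute_ani(g, g, aligner = fake(dup), mode = "ab")
  # 96 * 900 < 90 * 1020, so the 90% hit wins for g:1
  expect_equal(r3$ani_ab, mean(c(90, 95, 95)))
})

test_that("zero usable fragments in one direction fall back to the other", {
  g <- random_genome(2040, seed = 31, id = "g")
  none <- function(fragments, subject) {
    tibble::tibble(
      query_id = character(), pct_identity = numeric(),
      aln_length = numeric(), sstart = numeric()
    )
  }
  some <- function(fragments, subject) {
    tibble::tibble(query_id = "g:1", pct_identity = 98, aln_length = 1020, sstart = 1)
  }
  calls <- 0
  switcher <- function(fragments, subject) {
    calls <<- calls + 1
    if (calls == 1L) some(fragments, subject) else none(fragments, subject)
  }
  r <- compute_ani(g, g, aligner = switcher)
  expect_true(is.na(r$ani_ba))
  expect_equal(r$ani_mean, 98)
})

test_that("blastn backend agrees with the builtin on a small pair", {
  g <- random_genome(6120, seed = 40, id = "g")
  mut <- mutate_genome(g, 0.05, seed = 41)
  rb <- compute_ani(g, mut$genome, aligner = "blast")
  ri <- compute_ani(g, mut$genome, aligner = "builtin")
  expect_lt(abs(rb$ani_mean - ri$ani_mean), 0.5)
})

test_that("tidy and glance expose both directions and the mean", {
  g <- random_genome(2040, seed = 50, id = "g")
  r <- compute_ani(g, g, aligner = "builtin")
  td <- tidy(r)
  expect_equal(td$direction, c("ab", "ba"))
  expect_equal(td$ani, c(100, 100))
  expect_equal(glance(r)$ani_mean, 100)
  expect_equal(glance(r)$fragment_len, 1020L)
})
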