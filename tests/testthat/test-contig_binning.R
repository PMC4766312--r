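votes_for <- function(taxa, contig = "c1") {
  tibble::tibble(
    gene_id = paste0(contig, "_g", seq_along(taxa)),
    contig_id = contig, taxon = taxa
  )
}

test_that("the retention rule matches its stated examples", {
  out <- assign_contig_taxa(votes_for(rep("Euryarchaeota", 3)))
  expect_true(out$retained)
  expect_equal(out$majority_taxon, "Euryarchaeota")

  out <- assign_contig_taxa(votes_for(rep("Bacteroidetes", 2)))
  expect_false(out$retained)
  expect_equal(out$reason, "fewer than three genes")

  # dissent equal to exactly half is allowed
  out <- assign_contig_taxa(votes_for(c(
    "Euryarchaeota", "Euryarchaeota", "Bacteroidetes", "Proteobacteria"
  )))
  expect_true(out$retained)
  expect_equal(out$n_dissenting, 2L)

  # ... unless strict_half is requested
  out <- assign_contig_taxa(
    votes_for(c("Euryarchaeota", "Euryarchaeota", "Bacteroidetes", "Proteobacteria")),
    strict_half = TRUE
  )
  expect_false(out$retained)

  # modal tie rejects
  out <- assign_contig_taxa(votes_for(c("A", "A", "B", "B")))
  expect_false(out$retained)
  expect_equal(out$reason, "ambiguous majority")

  expect_error(assign_contig_taxa(votes_for(character())), "empty")
})

test_that("hitless genes count toward the total but not dissent", {
  taxa <- c("A", "A", "A", NA, NA, NA)
  out <- assign_contig_taxa(votes_for(taxa))
  expect_true(out$retained)
  expect_equal(out$n_genes, 6L)
  expect_equal(out$n_dissenting, 0L)
  out2 <- assign_contig_taxa(votes_for(taxa), hitless_in_denominator = FALSE)
  expect_equal(out2$n_genes, 3L)
})

test_that("voting is invariant under permutation of the vote order", {
  taxa <- c("A", "B", "A", NA, "C", "A")
  base <- assign_contig_taxa(votes_for(taxa))
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(seq_along(taxa)))
    expect_equal(
      assign_contig_taxa(votes_for(taxa[perm]))[-1],
      base[-1]
    )
  }
})

test_that("exhaustive enumeration up to six genes matches the brute-force oracle", {
  alphabet <- c("A", "B", "C", NA)
  all_votes <- list()
  expected <- list()
  k <- 0L
  for (n in 1:6) {
    grid <- do.call(expand.grid, c(rep(list(alphabet), n), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      k <- k + 1L
      taxa <- unname(unlist(grid[i, ]))
      cid <- sprintf("p%05d", k)
      all_votes[[k]] <- votes_for(taxa, contig = cid)
      o <- vote_rule_oracle(taxa)
      expected[[k]] <- tibble::tibble(
        contig_id = cid, retained = o$retained, majority = o$majority
      )
    }
  }
  got <- assign_contig_taxa(dplyr::bind_rows(all_votes))
  want <- dplyr::bind_rows(expected)
  got <- got[match(want$contig_id, got$contig_id), ]
  expect_equal(got$retained, want$retained)
  retained <- want$retained
  expect_equal(got$majority_taxon[retained], want$majority[retained])
})

test_that("unanimous contigs with at least three genes are always retained", {
  for (n in 3:6) {
    expect_true(assign_contig_taxa(votes_for(rep("X", n)))$retained)
  }
})

test_that("bin QC retains on contamination < 5% and sufficient length", {
  bins <- tibble::tibble(
    bin_id = c("b1", "b2", "b3", "b4", "b5"),
    concatenated_length = c(1.2e6, 2e6, 0.3e6, 1e6, 1e6),
    contamination = c(3.2, 6.0, 1.0, NA, 5.0)
  )
  out <- filter_bins(bins)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reason, c("ok", "contamination", "too short", "no QC", "contamination"))
  # the 0.8 Mb upper end of the working range is a configuration choice
  out2 <- filter_bins(bins, min_length = 8e5)
  expect_true(out2$retained[1])
})

test_that("planted vote tables realize their manifest exactly", {
  pattern <- tibble::tibble(
    n_contigs = c(3, 2, 2, 1),
    n_genes = c(3, 4, 2, 6),
    n_majority = c(3, 2, 2, 3),
    n_hitless = c(0, 0, 0, 1)
  )
  planted <- plant_contig_votes(pattern, c("Eury", "Bact", "Prot"), seed = 11)
  got <- assign_contig_taxa(planted$votes)
  man <- planted$manifest
  got <- got[match(man$contig_id, got$contig_id), ]
  expect_equal(got$retained, man$expected_retained)
  expect_equal(
    got$majority_taxon[man$expected_retained],
    man$majority_taxon[man$expected_retained]
  )
  expect_identical(
    plant_contig_votes(pattern, c("Eury", "Bact", "Prot"), seed = 11)$votes,
    planted$votes
  )
  expect_error(
    plant_contig_votes(tibble::tibble(n_contigs = 1, n_genes = 2, n_majority = 3),
                       c("A", "B"), seed = 1),
    "inconsistent"
  )
})
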