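#' Build a validated pipeline run configuration
#'
#' Collects every stage threshold (at its documented default), the
#' input paths and the seed into a flat named list. Unknown keys are
#' rejected, and the full configuration is echoed into every report
#' header so each filtering step is auditable.
#'
#' @param ... Named configuration entries; see Details.
#' @details Recognised keys, beyond `out_dir` and `seed`:
#' * profiling inputs `reads`, `n_subsample`, `hits_curated`,
#'   `hits_reference`, `taxon_map`, with thresholds `min_aln`, `min_id`,
#'   `max_evalue`, `min_fraction`, `exclude_labels`;
#' * bin inputs `contigs`, `bin_membership`, `votes`, `qc`,
#'   `marker_hits`, `markers`, `alignments`, `sample_bases`,
#'   `proteomes`, `reference_proteome`, with thresholds `min_genes`,
#'   `max_contamination`, `min_length`, `marker_max_evalue`,
#'   `marker_min_cov`, `recruit_min_identity`, `recruit_min_bases`,
#'   `pi_min_len`, `pi_bin_width`, `run_ani`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    out_dir = NULL, seed = 1L,
    reads = NULL, n_subsample = NULL,
    hits_curated = NULL, hits_reference = NULL, taxon_map = NULL,
    min_aln = 90, min_id = 80, max_evalue = 1e-5,
    min_fraction = 0.01, exclude_labels = "chloroplast",
    contigs = NULL, bin_membership = NULL, votes = NULL, qc = NULL,
    marker_hits = NULL, markers = "archaea_53",
    alignments = NULL, sample_bases = NULL,
    proteomes = NULL, reference_proteome = NULL,
    min_genes = 3L, max_contamination = 5, min_length = 5e5,
    marker_max_evalue = 1e-5, marker_min_cov = 0.80,
    recruit_min_identity = 95, recruit_min_bases = 50,
    pi_min_len = 30L, pi_bin_width = 0.1, run_ani = FALSE
  )
  given <- list(...)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, given), class = "run_config")
}

config_header <- function(config, stage) {
  vals <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, "")
  c(
    paste0("# stage: ", stage),
    paste0("# config: ", names(vals), " = ", vals)
  )
}

require_inputs <- function(config, keys) {
  missing <- keys[vapply(keys, function(k) is.null(config[[k]]), TRUE)]
  absent <- setdiff(keys, c(missing, "out_dir"))
  absent <- absent[!vapply(config[absent], function(p) {
    !is.character(p) || file.exists(p)
  }, TRUE)]
  problems <- c(
    if (length(missing) > 0) paste0("missing config key: ", missing),
    if (length(absent) > 0) {
      paste0("input file not found: ", unlist(config[absent]))
    }
  )
  if (length(problems) > 0L) abort(paste(problems, collapse = "; "))
}

write_report <- function(tbl, path, header) {
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the 16S community-profiling workflow
#'
#' Subsample (optional) -> candidate selection against the curated 16S
#' database -> best-named-hit classification against the reference
#' database -> taxon profile with chloroplast and <1% filters. Writes
#' `profile.tsv` (report with config header) and `profile_log.tsv`
#' (per-stage in/out counts) under `out_dir`.
#'
#' @param config A [run_config()] with at least `hits_curated`,
#'   `hits_reference`, `taxon_map` and `out_dir`.
#' @return The `taxon_profile`, invisibly.
#' @export
run_profile_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  require_inputs(config, c("hits_curated", "hits_reference", "taxon_map", "out_dir"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out
    )
  }
  hits_cur <- read_hits(config$hits_curated)
  keep_ids <- NULL
  if (!is.null(config$reads) && !is.null(config$n_subsample)) {
    reads <- read_fastq(config$reads)
    sel <- subsample_reads(reads, config$n_subsample, config$seed)
    keep_ids <- unique(sub("[/_][12]$", "", sel$id))
    note("subsample", nrow(reads), nrow(sel))
    hits_cur <- hits_cur[sub("[/_][12]$", "", hits_cur$query_id) %in% keep_ids, ]
  }
  cand <- select_candidate_reads(
    hits_cur,
    min_aln = config$min_aln, min_id = config$min_id,
    max_evalue = config$max_evalue
  )
  note("select_candidates", length(unique(hits_cur$query_id)), length(cand))
  hits_ref <- read_hits(config$hits_reference)
  hits_ref <- hits_ref[hits_ref$query_id %in% cand, , drop = FALSE]
  tm <- readr::read_tsv(config$taxon_map, col_types = "cc", progress = FALSE,
                        col_names = c("subject_id", "taxon"))
  assignments <- classify_reads(hits_ref, tm)
  note("classify", length(cand), sum(!is.na(assignments$taxon)))
  if (nrow(assignments) == 0L || all(is.na(assignments$taxon))) {
    warn("empty hit table or no classifiable reads: empty profile")
  }
  profile <- build_profile(
    assignments,
    min_fraction = config$min_fraction,
    exclude_labels = config$exclude_labels
  )
  note("profile", sum(!is.na(assignments$taxon)), nrow(profile))
  write_report(
    tibble::as_tibble(profile),
    file.path(config$out_dir, "profile.tsv"),
    config_header(config, "profile16s")
  )
  readr::write_tsv(dplyr::bind_rows(log), file.path(config$out_dir, "profile_log.tsv"))
  invisible(profile)
}

#' Run the per-bin characterisation workflow
#'
#' Vote-assigns contigs, applies bin QC (contamination/length),
#' computes marker completeness bounds, RPKG recruitment and pI
#' profiles, and writes one report row per bin (contigs, concatenated
#' length, GC%, completeness range, RPKG with abundance category, osmo
#' call) to `bins.tsv` under `out_dir`. Stages whose inputs are not
#' configured are skipped and noted; per-bin stage failures are
#' isolated into the `notes` column.
#'
#' @param config A [run_config()] with at least `contigs`,
#'   `bin_membership` and `out_dir`.
#' @return The per-bin report tibble, invisibly.
#' @export
run_bin_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  require_inputs(config, c("contigs", "bin_membership", "out_dir"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- read_fasta(config$contigs)
  membership <- readr::read_tsv(config$bin_membership, col_types = "cc",
                                progress = FALSE,
                                col_names = c("contig_id", "bin_id"))
  per_contig <- membership |>
    dplyr::left_join(
      tibble::tibble(contig_id = contigs$id, seq = contigs$seq),
      by = "contig_id"
    )
  if (anyNA(per_contig$seq)) {
    abort(paste0(
      "bin membership names contig(s) absent from FASTA: ",
      paste(head(per_contig$contig_id[is.na(per_contig$seq)], 3), collapse = ", ")
    ))
  }
  vote_note <- NULL
  if (!is.null(config$votes)) {
    votes <- readr::read_tsv(config$votes, col_types = "ccc", progress = FALSE,
                             col_names = c("gene_id", "contig_id", "taxon"))
    votes$taxon[votes$taxon %in% c("", "NA", "-")] <- NA_character_
    assign <- assign_contig_taxa(votes, min_genes = config$min_genes)
    dropped <- assign$contig_id[!assign$retained]
    vote_note <- paste0("vote-rejected contigs removed: ", sum(per_contig$contig_id %in% dropped))
    per_contig <- per_contig[!per_contig$contig_id %in% dropped, , drop = FALSE]
  }
  report <- per_contig |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n_contigs = dplyr::n(),
      concatenated_length = sum(nchar(.data$seq)),
      gc_pct = 100 * sum(
        Biostrings::letterFrequency(
          Biostrings::DNAStringSet(gsub("[^ACGT]", "N", .data$seq)), c("G", "C")
        )
      ) / sum(Biostrings::letterFrequency(
        Biostrings::DNAStringSet(gsub("[^ACGT]", "N", .data$seq)), c("A", "C", "G", "T")
      )),
      .groups = "drop"
    )
  notes <- setNames(rep("", nrow(report)), report$bin_id)
  add_note <- function(bin, msg) {
    notes[bin] <<- paste0(notes[bin], ifelse(nzchar(notes[bin]), "; ", ""), msg)
  }
  # bin QC
  if (!is.null(config$qc)) {
    qc <- readr::read_tsv(config$qc, col_types = "cdd", progress = FALSE,
                          col_names = c("bin_id", "contamination", "strain_heterogeneity"))
    report <- dplyr::left_join(report, qc, by = "bin_id")
  } else {
    report$contamination <- NA_real_
    report$strain_heterogeneity <- NA_real_
  }
  report <- filter_bins(report,
    max_contamination = config$max_contamination,
    min_length = config$min_length
  )
  # completeness
  report$completeness <- NA_character_
  if (!is.null(config$marker_hits)) {
    ms <- if (inherits(config$markers, "marker_set")) config$markers else marker_set(config$markers)
    mh <- readr::read_tsv(config$marker_hits, col_types = "cccddd", comment = "#",
                          progress = FALSE,
                          col_names = c("bin_id", "marker_id", "gene_id",
                                        "evalue", "hcov", "qcov"))
    for (b in report$bin_id) {
      res <- tryCatch(
        {
          ev <- evaluate_markers(
            mh[mh$bin_id == b, -1], ms,
            max_evalue = config$marker_max_evalue, min_cov = config$marker_min_cov
          )
          completeness_bounds(ev, ms)$label
        },
        error = function(e) {
          add_note(b, paste0("completeness failed: ", conditionMessage(e)))
          NA_character_
        }
      )
      report$completeness[report$bin_id == b] <- res
    }
  }
  # recruitment
  report$rpkg <- NA_real_
  report$abundance <- NA_character_
  if (!is.null(config$alignments) && !is.null(config$sample_bases)) {
    aln <- if (grepl("\\.sam$", config$alignments)) {
      read_sam(config$alignments)
    } else {
      read_paf(config$alignments)
    }
    recruited <- aln |>
      filter_recruit(config$recruit_min_identity, config$recruit_min_bases) |>
      recruit_sample(
        setNames(report$concatenated_length, report$bin_id),
        config$sample_bases
      )
    report$rpkg <- recruited$rpkg[match(report$bin_id, recruited$target_id)]
    report$abundance <- as.character(
      recruited$category[match(report$bin_id, recruited$target_id)]
    )
  }
  # pI profile and osmotic-strategy call
  report$mode_pI <- NA_real_
  report$osmo_call <- NA_character_
  if (!is.null(config$proteomes)) {
    pmap <- readr::read_tsv(config$proteomes, col_types = "cc", progress = FALSE,
                            col_names = c("bin_id", "path"))
    ref_profile <- NULL
    if (!is.null(config$reference_proteome)) {
      ref_profile <- pi_histogram(
        read_fasta(config$reference_proteome, kind = "protein"),
        min_len = config$pi_min_len, bin_width = config$pi_bin_width,
        genome_id = "reference"
      )
    }
    for (b in intersect(report$bin_id, pmap$bin_id)) {
      res <- tryCatch(
        {
          prof <- pi_histogram(
            read_fasta(pmap$path[pmap$bin_id == b][1], kind = "protein"),
            min_len = config$pi_min_len, bin_width = config$pi_bin_width,
            genome_id = b
          )
          call <- if (!is.null(ref_profile)) {
            classify_osmo_strategy(prof, ref_profile)$call
          } else {
            NA_character_
          }
          list(mode = prof$mode_pI, call = call)
        },
        error = function(e) {
          add_note(b, paste0("pI failed: ", conditionMessage(e)))
          list(mode = NA_real_, call = NA_character_)
        }
      )
      report$mode_pI[report$bin_id == b] <- res$mode
      report$osmo_call[report$bin_id == b] <- res$call
    }
  }
  report$notes <- unname(notes[report$bin_id])
  # optional ANI matrix over retained bins
  if (isTRUE(config$run_ani) && sum(report$retained) >= 2L) {
    retained_ids <- report$bin_id[report$retained]
    pairs <- utils::combn(retained_ids, 2L)
    ani_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      ga <- per_contig[per_contig$bin_id == a, c("contig_id", "seq")]
      gb <- per_contig[per_contig$bin_id == b, c("contig_id", "seq")]
      names(ga) <- names(gb) <- c("id", "seq")
      res <- glance(compute_ani(ga, gb))
      tibble::tibble(
        bin_a = a, bin_b = b, ani_mean = res$ani_mean,
        conserved_fraction_mean = res$conserved_fraction_mean
      )
    })
    readr::write_tsv(ani_tbl, file.path(config$out_dir, "ani.tsv"))
    attr(report, "ani") <- ani_tbl
  }
  header <- config_header(config, "bin_workflow")
  if (!is.null(vote_note)) header <- c(header, paste0("# ", vote_note))
  write_report(report, file.path(config$out_dir, "bins.tsv"), header)
  invisible(report)
}
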