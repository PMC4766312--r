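---
title: "Methods: community profiles, genome bins, ANI, RPKG and proteome pI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community profiles, genome bins, ANI, RPKG and proteome pI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brinemag)
library(dplyr)
```

brinemag implements the downstream, rule-based stages of a shotgun
metagenome study of hypersaline alkaline brines: the stages that turn
similarity-search tables, read alignments and predicted sequences into
community profiles, quality-controlled genome bins and per-population
statistics. Upstream heavy lifting — read trimming, assembly, gene
prediction, HMM searches, differential-coverage clustering,
contamination estimation and the read mapping itself — is deliberately
left to the established external tools whose tabular outputs this
package consumes. What brinemag owns is the decision logic applied to
those tables, because that logic is what determines the reported
biology and is what must be reproducible.

## 16S read profiling

Shotgun reads carrying 16S rRNA fragments are found by comparing a
read subsample against a small curated 16S database; a read is a
candidate when its best hit aligns over at least 90 bases with at
least 80% identity at an e-value of at most 1e-5
(`select_candidate_reads()`). All three bounds are inclusive: the
rules are stated as thresholds without strictness, and inclusive
reading is the convention we fix and expose as configuration.
Candidates are then classified against a full reference database by
their *best named* hit (`classify_reads()`): hits whose subjects carry
no top-level taxon name are skipped in score order, so a read is never
discarded merely because its single best subject is unnamed. Score is
bit score when available, identity otherwise; exact ties break to the
lexicographically smallest subject id and are flagged, making
classification invariant to input order.

`build_profile()` removes chloroplast-labelled assignments first, then
computes fractions over the remaining assigned reads and moves taxa
under 1% to an excluded tier. The order matters — the filters are
applied in the sequence just described, and fractions are recomputed
after chloroplast removal — and both the cutoff and the excluded
labels are parameters echoed in the result.

## Contig vote-binning and bin QC

Each predicted gene on a contig votes with the taxon of its best
database hit. A contig is retained when it has at least three genes
and not more than half of its genes hit taxa different from the
majority (`assign_contig_taxa()`). Two readings of that rule are
genuinely open and we fix both explicitly:

* *"not more than half"* is inclusive — dissent equal to exactly half
  is allowed (a `strict_half` flag reverses this);
* genes with no hit count toward the gene total but not toward
  dissent, since they hit nothing (`hitless_in_denominator` reverses
  this).

A tie for the modal taxon rejects the contig rather than picking a
winner arbitrarily: a tie means at least half the genes disagree with
any candidate taxon. The whole rule is tested exhaustively against a
brute-force oracle over every vote pattern of up to six genes.

Bin-level QC (`filter_bins()`) retains bins with contamination
strictly below 5% (contamination and strain heterogeneity come from an
external QC tool and are consumed, not computed) and concatenated
length of at least 0.5 Mb. The working range quoted for acceptable
draft length is 0.5–0.8 Mb; we default to its lower end and expose
`min_length`.

## Fragment ANI and conserved DNA

`compute_ani()` implements fragment-based average nucleotide identity:
each genome is cut into consecutive 1020-bp fragments
(`fragment_genome()`; the sub-length terminal fragment is dropped by
default), each fragment is searched against the other genome with a
local aligner, and a fragment enters the ANI mean when its best hit
covers at least 70% of the fragment at 30% identity or better. The
conserved-DNA fraction is the length of fragments whose best hit
reaches 90% identity, divided by query genome length. These constants
are the published parameterisation of the classical fragment-ANI
method; all are arguments. Identity is matched bases over alignment
columns including gaps, consistent with standard search-tool output.
Both directions are computed and the mean reported, since a single ANI
per genome pair is the conventional summary; `mode` gives one-way
behaviour, and `tidy()` exposes the per-direction values.

Two aligner backends satisfy the same contract (best local hit per
fragment with identity, aligned length and subject position):

* `ani_aligner_builtin()` — exact Smith–Waterman via
  `Biostrings::pairwiseAlignment()` with unit match/mismatch scores;
  exact but quadratic, intended for fragments against subjects up to a
  few tens of kb. On self-comparison it returns ANI = 100 exactly.
* `ani_aligner_blast()` — shells out to `blastn -task blastn` with
  unit scores, dust off and a large final X-dropoff so fragment
  alignments extend end to end; this is the genome-scale backend.

On synthetic pairs mutated at per-base substitution rate *d*, both
backends recover ANI within half a percentage point of 100(1 − *d*)
for *d* up to 0.10 (tested at 100 kb with blastn, five seeds per
divergence). Local alignment can in principle bias identity upward by
trimming mismatch-dense fragment ends; with 1020-bp fragments and the
scoring above the observed bias is well inside that half-point band.

## Marker-gene completeness bounds

Completeness of a draft genome is estimated from the presence of
single-copy marker genes: 112 genes essential in bacteria or 53 core
genes in archaea. From a profile-HMM search table, a marker is
*loosely* present with any hit at e-value ≤ 1e-5 and *strictly*
present when a qualifying hit also has both hit and query coverage
above 80% (`evaluate_markers()`; the 0.80 threshold is exclusive). The
strict tier can only shrink the detected set, so strict detections
give the lower completeness bound and loose detections the upper
(`completeness_bounds()`); because the underlying phrasing of which
filter feeds which bound is ambiguous, a `swap_bounds` flag provides
the other reading. Multi-copy markers count once — redundancy is a
contamination signal handled elsewhere. The coverage denominators
(model vs sequence length) are taken as given in the input table; the
package requires both coverages rather than guessing their definition.

The bundled marker-set files carry placeholder identifiers
(`bac_essential_001`, ...) generated with the package: the computation
depends only on identifier matching, and users with real HMM accession
lists can point `marker_set()` at their own file.

## Read recruitment and RPKG

An alignment recruits its read when it has at least 95% nucleotide
identity over at least 50 aligned bases (`filter_recruit()`, both
inclusive). Abundance is expressed as RPKG,

$$\mathrm{RPKG} = \frac{n_\text{recruited}}
  {(L_\text{genome}/10^3)\,(B_\text{sample}/10^9)},$$

recruited reads per kilobase of target genome per gigabase of sampled
metagenome. The unit's full name is sometimes expanded inconsistently
in the literature; the implemented definition is the one above, with
sample size measured in bases of the (sub)sampled read set, not read
count. Each read counts once per target (best alignment per
read–target pair), reads hitting several targets count for each, and
individual reads — not pairs — are counted by default.

Presence and abundance bands follow the working convention: below
RPKG = 2 a population is called absent, [2, 20) low, [20, 120]
moderate, above 150 high. The interval (120, 150] is left undefined by
that convention; `classify_abundance()` maps it to moderate and flags
it rather than inventing a silent boundary.

## Proteome pI profiles and osmotic strategy

Halophiles using the "salt-in" strategy (intracellular KCl) carry
strongly acid-shifted proteomes; "salt-out" organisms (organic
osmolytes) do not. `compute_pI()` finds each protein's isoelectric
point by bisection on the Henderson–Hasselbalch net charge, which is
strictly decreasing in pH, so convergence is guaranteed; the result is
rounded at the tolerance's precision (default 1e-4) so closed-form
values land on their histogram boundary. The pKa table defaults to the
classical EMBOSS `iep` constants (C-terminus 3.6, Asp 3.9, Glu 4.1,
His 6.5, Cys 8.5, N-terminus 8.6, Tyr 10.1, Lys 10.8, Arg 12.5);
because pI values are table-dependent, every profile records the table
it used. Unknown residues carry no ionizable group.

`pi_histogram()` drops proteins shorter than 30 residues and bins pI
values into left-closed, right-open 0.1-pH bins over [0, 14), with
exactly 14 clamped into the last bin. The classification step is done
by eye in comparative studies; `classify_osmo_strategy()` instead
applies explicit, reported criteria — modal pI at most 5.5, acidic
fraction (pI < 7) at least 0.6, and a mode below the reference
proteome's — and anything passing neither the salt-in nor the
no-shift pattern is `indeterminate`. These thresholds are a stated
convention of this package, not a community standard, and are
parameters of the call.

## Synthetic data: what it emulates and what it does not

The generators in this package produce every input the pipeline
consumes, each with a manifest sufficient to recompute the expected
output:

* `mutate_genome()` plants independent per-base substitutions, so ANI
  recovery can be checked against a binomial oracle;
* `simulate_reads()` draws 150-bp (optionally paired) reads with
  uniform start positions and independent substitution errors, and
  emits ground-truth alignments in PAF layout. Abundance is defined as
  relative coverage — expected reads ∝ abundance × genome length — so
  RPKG recovers abundance ratios directly;
* `plant_contig_votes()` and `plant_marker_hits()` realise exact
  count patterns for the rule-based stages;
* `simulate_proteome()` solves residue compositions against the
  package's own pI solver (bisection on the acid share of charged
  residues, then a local integer refinement), so the test loop is
  closed rather than calibrated against an external program. Proteins
  are His-rich when the target pI falls in the 6.5–8.5 titration gap,
  where achievable composition pIs are otherwise sparse.

These generators are statistical caricatures: substitution-only errors
(indels behind a flag), no platform-specific error profiles or quality
decay, no assembly or binning artifacts, no compositional bias, and
generated proteomes occupy a narrow, controlled pI band rather than
the broad bimodal distribution of real proteomes. Passing tests
therefore demonstrate that the decision rules and normalisations are
implemented correctly under their stated assumptions — not that the
upstream tools, nor real-data idiosyncrasies, are modelled.

## Numerical and design choices

* All stated thresholds are inclusive unless a source phrase forces
  strictness ("below 5%", "coverage > 80%" are strict/exclusive where
  noted above).
* Ambiguous bases are excluded from GC denominators by default
  (`gc_content(exclude_ambiguous = FALSE)` reverses).
* Subsampling treats a read pair as one unit, drawn without
  replacement and bit-reproducible under a fixed seed.
* Best hits everywhere use a deterministic tie-break (score, then
  identity, then lexicographic subject id; fragment hits tie-break by
  subject position) so every stage is permutation-invariant.
* Completeness is displayed as `lower–upper` with one decimal; exact
  values are kept internally.
* Workflow reports echo the full configuration in their header and are
  byte-identical on rerun with the same config and seed.

Default problem sizes used by the test-suite and the acceptance
script — 100 kb genomes for ANI recovery, 10^5 reads for abundance
recovery, 500-protein proteomes, 10^4 reads for profile recovery —
were chosen as the smallest sizes at which the binomial/multinomial
sampling error is comfortably inside each check's tolerance.

## Known limitations

* The built-in aligner is quadratic; genome-scale ANI requires the
  blastn backend (or any backend honouring the contract).
* RPKG counts individual reads; mate-aware counting would halve values
  but not change ratios.
* The specificity property of the 95% recruitment filter against
  diverged decoy genomes is not covered by the simulator's
  ground-truth alignments (that would require running a real mapper,
  which is out of scope).
* `classify_osmo_strategy()` encodes a convention, not a validated
  classifier; borderline ("salt-in to some extent") proteomes will
  return `indeterminate`.

```{r example, eval = FALSE}
# a compact end-to-end sketch on synthetic data
g <- random_genome(1e5, seed = 1, id = "anc")
mut <- mutate_genome(g, 0.02, seed = 2)
compute_ani(g, mut$genome)             # ~98% ANI

ms <- marker_set("archaea_53")
planted <- plant_marker_hits(ms, 42, 45, seed = 3)
completeness_bounds(evaluate_markers(planted$hits, ms), ms)  # 79.2–84.9

acid <- pi_histogram(simulate_proteome(500, 4.5, seed = 4)$proteome)
ref  <- pi_histogram(simulate_proteome(500, 7.0, seed = 5)$proteome)
classify_osmo_strategy(acid, ref)      # salt-in-like
```
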