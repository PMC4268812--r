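---
title: "Methods: pan-genome base classification for genome trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome base classification for genome trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When several de novo assemblies of related genomes (the motivating case is
three divergent rice varieties) are compared by whole-genome alignment,
every base of every assembly can be placed in one of the seven sectors of a
three-way Venn diagram: core (aligned to both other genomes), shared with
exactly one other genome, or genome-specific (aligned to neither).
Genome-specific sequence is the interesting fraction — it is invisible to
reference-mapping approaches — but most of it is unassembled high-copy
repeat. The method therefore combines two orthogonal signals:

1. **Alignment**: anchor-based whole-genome alignment decides which bases
   are shared.
2. **k-mer coverage from unassembled reads**: the per-position multiplicity
   of canonical 21-mers in a read sample separates single-copy sequence
   (coverage near the read depth) from repeats (coverage proportional to
   copy number), independently of assembly quality.

A genome-specific region is accepted as *non-repetitive, real* sequence
when it is at least 100 bp long, has mean self-read k-mer coverage between
10x and 100x (below 10x suggests assembly artifact, above 100x repeat), and
mean coverage below 10x in both other genomes' reads (which confirms the
sequence is genuinely absent there, not merely unassembled). The same
coverage tracks support presence/absence calls for individual loci: a locus
is present in a genome when most of its positions are covered at >= 10x by
that genome's reads after masking repeat-derived spikes (> 100x).

## Pipeline stages and their parameters

**Anchoring.** Anchors are maximal exact matches of length >= 30 bp
(`min_match`) that are unique in the reference: the matched reference
substring occurs exactly once on the reference forward strand. (Uniqueness
semantics are a genuine design choice; reference-side uniqueness mirrors
the default behaviour class of the MUMmer family. A maximal-match mode
without the uniqueness filter is available via `unique_ref = FALSE`.)
Non-ACGT characters match nothing, so anchors never span scaffold gaps.

**Clustering.** Anchors on one (reference sequence, query sequence, strand)
triple chain greedily in reference order when the gap to a cluster tail is
at most 90 bp (`max_gap`) on both axes and the diagonal drift is at most 5
times the gap (`diag_band`). Small anchor overlaps (frequent around tandem
micro-repeats) are resolved by trimming the later anchor. Clusters whose
summed anchor length is below 65 bp (`min_cluster`) are discarded. These
defaults are the sensitive settings commonly used for cross-variety plant
genome comparison.

**Extension.** Gaps between chained anchors are closed by global alignment
with unit mismatch/indel costs (the cost scheme is not dictated by the
problem; unit costs keep identity interpretable as matched columns over
total columns). Block ends extend greedily while local identity stays above
0.65. Indel events of <= 5 bp (`small_indel_cutoff`) are pooled with
substitutions as "SNPs and small indels"; larger events are reported
individually. A gap larger than `max_dp_gap` (2 kbp) splits the block
rather than risking a quadratic blow-up.

**One-to-one filtering.** The difference summary must not double-count
repeat-induced alternative alignments, so a maximum-weight subset of blocks
is selected such that no two kept blocks overlap in reference or in query
coordinates, with weight = alignment length x identity (= matched columns).
Conflict components of up to 20 blocks are solved exactly by
branch-and-bound; larger components (rare; conflicts are local) fall back
to a greedy sweep by weight. An exact small-component solver was chosen
over pure chaining because mutually consistent subsets are not necessarily
collinear — inversions and translocations must survive filtering to be
counted.

**Difference summary.** Blocks are walked in query order: a strand change
between adjacent blocks is an inversion; a reference-sequence change is a
translocation; same-reference blocks out of order, or in order but
separated by more than `relocation_gap` (10 kbp; a free parameter, the
structural tests are written to be robust to it), are relocations.

**Classification.** Unaligned regions are computed from the *unfiltered*
(repeat-inclusive) block set — a base counts as shared if anything aligns
there, so copy-number differences are not mistaken for novel sequence.
The four sectors touching a focal genome are derived by exact interval
algebra, and partition the genome by construction; the partition is
asserted, not assumed, in the tests.

**Gene sector assignment.** A gene may straddle sector boundaries, so
exonic bases are summed per sector across *all* transcripts (an exon shared
by two transcripts counts twice — the majority is over transcript-exon
bases, not genomic bases) and the gene goes to the sector with the most
bases. Exact ties resolve toward the more-shared sector (core, then
pairwise, then specific): conservative against overcalling novelty.

**Reporting.** Mean region sizes in the region tables are the integer floor
of total/count — the unique rule consistent with all six printed mean
values of the published genome-specific region tables this report format
mirrors. Coverage percentages are printed to one decimal, half-up.
Contigs are scaffold pieces split at runs of >= 1 N (`min_gap_run`,
exposed); contig count and N50 are over contigs > 1 kbp.

## The synthetic trio: what it emulates and what it does not

`simulate_trio()` is the package's validation instrument, not a fixture: it
plants a known pan-genome and the rest of the package must recover it.

* **Composition.** A 1 Mbp core in 20 segments, five 2 kbp segments per
  pairwise sector, ten specific segments per genome spanning 0.5–5 kbp, and
  one genome-private tandem array of 50 exact copies of a 400 bp unit per
  genome. These scales mirror the real analysis downscaled ~300-fold: ten
  kbp-scale specific islands per megabase, separated by ~100 kbp — the same
  order as the roughly one-per-162-kbp spacing reported for real
  genome-specific regions.
* **Divergence.** Each genome's copy of a shared segment is mutated
  independently at `snp_rate` substitutions/bp (default 0.005, so ~1%
  pairwise divergence — the published alignment identities between the rice
  subpopulations are ~98.9%) plus 1–5 bp indels at `small_indel_rate`
  (2e-4/bp). No divergence value is stated for the real trio's shared
  regions; 0.005 is a configurable default chosen to land in the observed
  identity range.
* **Layout.** Segments are concatenated in seeded random order, one
  scaffold per genome, separated by 100 bp N runs. The N gaps play the role
  of scaffold gaps and serve a precise purpose: maximal exact matches
  cannot chance-extend across a planted junction (without a junction
  barrier, an exact matcher extends ~1/3 bp on average past every
  boundary, and per-base truth recovery could never be exact). Because N
  aligns to nothing, gap bases are observationally genome-specific; truth
  labels them with the genome's own specific sector and records their
  origin (`gap`) separately from planted segments and repeats, so
  region-level benchmarks can target planted segments only.
* **Placement.** Genome-specific segments (and the repeat array) are
  interleaved into distinct gaps of the shared-segment order, so no two
  specific-sector segments are adjacent and each planted region is
  recoverable as a distinct maximal run — as in the real genomes, where
  specific regions are isolated kbp-scale islands.
* **Genes.** Gene models (1 transcript, 1–4 exons, 60 bp terminal UTRs) are
  placed wholly inside segments at 2 per 10 kbp, and carried identically by
  every genome sharing the segment; indel mutations shift annotation
  coordinates through an explicit coordinate projection. Density is set so
  that the largest specific segments carry a gene (giving the genic-region
  and presence/absence paths something to find) while core segments carry
  ~10 each. Boundary-spanning genes are deliberately absent: gene-sector
  truth stays unambiguous.
* **Reads.** Single-end 100 bp reads, uniform position and strand, 60x
  depth, optional per-base substitution errors (default 0). Expected
  single-copy k-mer coverage is `depth * (1 - (k-1)/L)` = 48x, inside the
  [10,100]x acceptance window of the specific-region criteria.

What it does *not* emulate: paired ends and insert sizes, quality-score
realism, sequencing-error spectra (errors are uniform substitutions),
assembly fragmentation and collapse (the "assemblies" are perfect by
construction), transposon families shared across genomes, and segmental
duplication. Passing the recovery benchmarks therefore demonstrates the
*logic* of the classification and coverage machinery, not robustness to
assembly artifacts — which is exactly why the coverage criteria that guard
against such artifacts are tested with constructed profiles as well.

## Numerical and degenerate-input choices

* Interval sets are 0-based half-open everywhere internally; GFF3 converts
  on read/write (1-based inclusive), BED round-trips unchanged. Touching
  intervals merge: the algebra is over base sets, not records.
* Mode estimation excludes multiplicities below 10 (the error peak) and
  breaks ties toward the smaller multiplicity; an empty histogram above the
  cutoff is an explicit "no signal" error, not a 0.
* The repeat boundary is strictly greater-than 100x; the self-coverage
  window [10,100] is inclusive at both ends; cross-coverage must be
  strictly below 10x. The presence/absence fractions (0.8 present /
  0.2 absent, `ambiguous` between) are operating points exposed as
  arguments; a locus whose every position is repeat-masked is `ambiguous`.
* Coverage profile values attach to the k-mer's start position; the last
  k-1 positions of a sequence carry no value, and region means are over
  start positions only.
* A gene with zero exonic bases, an empty interval with start >= end, a
  read length exceeding the shortest scaffold, and a repeat plan exceeding
  the genome all fail loudly with specific errors.
* All randomness passes through R's RNG seeded from the configuration;
  segment layout draws from per-genome sub-seeds *before* mutation so that
  raising mutation rates cannot reshuffle the planted layout (a property
  the invariant tests pin down). Identical configuration and seed give
  byte-identical FASTA/GFF3/BED/FASTQ outputs.

## Problem sizes used in validation

The standard recovery benchmark (tests and the acceptance script) uses the
defaults above: three ~1.07 Mbp genomes and ~643k reads per genome. Oracle
equivalence is checked exhaustively at small scale: coverage profiles
against brute-force window lookup on 1 kbp sequences, anchoring against
exhaustive enumeration on <= 300 bp pairs over 100 seeds, interval algebra
against per-base bitmaps on 1,000-interval sets, and one-to-one filtering
against exponential search on <= 12 blocks. These sizes make every oracle
exact while keeping the full suite to a few minutes on one core.

## Known limitations

* The aligner is designed for closely related genomes (>= ~90% identity in
  shared regions); anchoring at `min_match = 30` loses sensitivity beyond
  a few percent divergence and there is no protein-space fallback.
* Relocation/translocation counts depend on the operational adjacency
  definitions above; different structural-variant callers draw these lines
  differently, so absolute counts are not comparable across tools.
* `k` is capped at 31 (2-bit packing in 64 bits) and must be odd so every
  canonical k-mer is unambiguous (no reverse-complement palindromes).
* One-to-one filtering is exact only per conflict component up to 20
  blocks; a pathological component (hundreds of mutually overlapping
  blocks, e.g. aligning a tandem array to itself) falls back to greedy
  selection.
* Coverage criteria are evaluated per specific region as a whole; a region
  that concatenates unique and repetitive sequence in one run is judged on
  its mean, which can reject real unique sequence adjacent to repeat (the
  simulator's non-adjacent placement sidesteps this; real data does not).
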