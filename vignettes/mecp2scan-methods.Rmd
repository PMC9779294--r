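---
title: "Methods: isoform annotation and consensus segment calling at a MECP2-like locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform annotation and consensus segment calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecp2scan)
```

# Scope and model

`mecp2scan` formalizes two kinds of analysis around one X-linked,
minus-strand, four-exon locus: (a) structural comparison of
splice-variant protein isoforms against the two established reference
isoforms, and (b) reduction of multi-sample browser tracks (histone-PTM
ChIP, DNase/ATAC accessibility, bisulfite methylation fractions) to
discrete, labelled genomic segments and their co-localization. Both
analyses are usually done by eye in a genome browser; every step here is
a deterministic computation with exposed parameters.

# Coordinate conventions

Genomic coordinates are 1-based inclusive internally (browser display
convention); BED/bedGraph I/O converts to 0-based half-open at the file
boundary. Positions are reported relative to the transcription start
site, defined as the transcription-direction first nucleotide of exon 1
(including the 5' UTR), anchored per assembly (hg19 chrX:153,363,188;
hg38 chrX:154,097,717 for the real locus). **Positive values run in the
transcription direction** (into and beyond the gene body), negative
values are promoter-side; for a minus-strand gene the transform is
`relative = TSS − genomic`. This is the only convention simultaneously
consistent with the published fragment anatomy — the intragenic S1–S7 and
A1–A4 series carry positive coordinates, and the fragment at +77.7 kb
contains the promoter of the downstream neighbour gene — and the package
asserts that consistency in its test suite (verbal descriptions of the
convention elsewhere are contradictory, so the printed coordinates were
taken as authoritative). Fragment coordinates are entered in kb at 0.1 kb
precision and expanded to integer bases (×1000) before any arithmetic.

# Alignment and anchored matching

`global_align()` is a full Needleman–Wunsch/Gotoh dynamic program over
both sequence lengths with affine gaps: a gap of length $k$ costs
$g_{open} + k\,g_{ext}$ (defaults −10, −1), substitution scores from
BLOSUM62. No parameter set is published for the original web-tool
alignments, so these community defaults are the package's choice; the
test suite pins the implementation to an exhaustive enumeration over all
monotone alignments on short pairs and to an independent library aligner
under the identical scoring convention. Traceback ties are broken
deterministically (substitution, then gap-in-query, then gap-in-ref), so
identical inputs always produce identical alignments.

Downstream classification never uses raw aligned-identity columns
directly: a reference position counts as *matched* only inside an
anchored run of ≥ `min_anchor` (default 6) consecutive identical
columns. Rationale: the isoforms of interest contain *novel* blocks
(alternative N-termini, intron-translated C-termini) that align against
the reference as mismatch columns; roughly 1 in 20 such columns is an
identity by chance, and counting those would turn a clean C-terminal
truncation into a spurious internal gap. Six residues makes a chance
anchor (p ≈ 20⁻⁶ per offset) negligible at protein scale while keeping
real shared blocks (the shortest here is the 8-residue exon-2 remnant)
anchored. The same 6-residue floor applies to exon-provenance labelling,
where overlapping candidate matches are resolved longest-first, then
5'-most exon, then position.

# Terminal differences and fragment origin

Distinctive-terminal counts are defined via the longest common
suffix/prefix (not via alignment): for two isoforms sharing a suffix of
length $L$, the distinctive N-terminal counts are $|a|-L$ and $|b|-L$.
This definition reproduces the canonical 21/9 split of the two
established isoforms exactly and is symmetric in its arguments. Novel
fragments are located by scanning all six frame translations of the
locus with per-offset Hamming identity (no gaps) — sufficient because the
fragments being traced are contiguous translations — reporting the
overlapped exon/intron when identity ≥ `min_identity` (default 0.9,
far above the ~0.05 chance identity of unrelated peptides), ties broken
by 5'-most genomic start.

# Domain projection

A domain $[s, e]$ on the reference isoform is classified from the set
$M$ of matched reference positions inside it: coverage $=|M|/(e-s+1)$;
`complete` at coverage 1; `missing` at coverage ≤ `missing_threshold`
(default 0.1 — a fragmentary match below one tenth of the domain is
reported as absent, matching how summary tables mark "-" cells);
otherwise the unmatched positions' layout (prefix / suffix / interior)
selects `n_incomplete`, `c_incomplete`, `n_and_c_incomplete` or
`internal_gap` (interior gaps keep their terminal flags for rendering,
e.g. "C-term. incompl, missing fragment inside"). One special case: when
the unmatched prefix is consumed by a leading divergent block in which
the query *does* align residues (an alternative N-terminus rather than a
plain truncation), the category is `alternative_n_terminus` ("Possible
different N-terminus"). Identity, not similarity, is required for a
match — the published tables treat any substitution-free presence as
"✓", and the single global threshold of 0.1 reproduces both packaged
expectation tables cell-for-cell; any cell that failed to reproduce
would be emitted in a discrepancy report rather than silently matched.
Exon rows are computed from provenance labels (alignment-free) with the
same status logic; their four-value presence vocabulary is extended by
the same terminal/interior flags because one published exon cell is a
compound status.

Queries are aligned to both reference isoforms and the better-scoring
one is reported as the matching reference (E1-like N-termini match the
E1-style reference); classification always uses the alignment to the
domain-bearing reference, where the coordinates are defined.

# Synthetic data: what it emulates, and what it does not

The generator is the package's ground-truth instrument, not a model of
sequencing. `simulate_locus()` builds a locus whose exon coding parts are
back-translated from generated peptides (so exon phases are consistent
by construction and both exon 1 and exon 2 carry start codons);
`simulate_isoforms()` applies *declarative* edits — kept residue ranges
of an E1- or E2-style base product plus optional novel C-terminal
fragments taken from stop-free windows of a named intron/exon frame — so
the per-residue origin and the expected domain status of every variant
are exact by construction, not estimated. `simulate_tracks()` draws
per-bin Poisson counts (default background mean 5 per 200-bp bin, a
typical pileup-density scale) multiplied by the enrichment fold inside
planted segments for the carrying subset of tracks;
`simulate_methylation()` draws per-bin Beta fractions (background
Beta(8,2), mean 0.8; hypomethylated Beta(1,9), mean 0.1) independently
per sample. Defaults mirror the study conditions the package targets: a
150 kb view, 7 signal tracks (one per brain region in a typical panel),
6 methylation samples (one per donor age), kb-scale planted segments at
8-fold enrichment.

Deliberately not emulated: read-level noise (FASTQ), mappability/GC
bias, fragment-size effects, spatially correlated background, diploid or
allele-specific methylation, and inter-sample depth differences beyond
what per-track quantile normalization absorbs. Passing the recovery
benchmarks therefore shows the callers are correct and well calibrated
*for this noise family*; it does not certify performance on real tracks,
whose backgrounds are heavier-tailed and spatially structured.

The packaged reference bundle (`synthetic_mecp2_bundle()`, serialized
under `inst/extdata/synthetic_*`) is a deterministic instance of this
generator standing in for database objects that cannot be fetched at
build time: gene topology and the two canonical N-termini
(MAAAAAAAPSGGGGGGEEERL / MVAGMLGLR) are real; all downstream residues
and the domain coordinates are generated placements chosen to be
mutually consistent with the documented architecture of each database
isoform (which exons each contains, where it truncates, which fragments
are intron-translated and which share termini). Conclusions about real
residue numbers must not be read off these fixtures; replace them with
database FASTA and measured domain coordinates for live use.

# Segment and HMR calling

Signal tracks are averaged onto a fixed bin grid (`bin_size`, default
200 bp — the working resolution of the planted segments and a common
display bin). Per track, a bin is *enriched* when its value reaches that
track's `enrich_quantile` within the region **and is positive** (so an
all-zero track enriches nothing, while a constant positive track is
enriched everywhere — both degenerate cases are exercised in tests). The
quantile is per-track, absorbing depth differences the way auto-scaled
browser display does. The default quantile is 0.9: calibration on the
synthetic ground truth showed that a 0.75 cut admits ~23% of background
bins per track under Poisson noise, which after consensus voting and
2-kb gap merging produces spurious consensus segments and degrades
planted-segment recovery below the package's own 0.8-Jaccard benchmark;
at 0.9 the consensus false-call rate drops to a few bins per 100 kb
while kb-scale 8-fold segments clear the cut in every track. Consensus
requires `consensus_fraction` (default 0.7, "most samples") of tracks;
consensus bins merge across gaps ≤ `merge_gap` (default 2 kb; the
segments of interest are kb-scale) and calls shorter than `min_length`
(default 500 bp) are dropped. Labels are assigned in
transcription-direction order when a gene model is supplied.

HMRs are per-sample maximal runs of bins with mean fraction ≤
`hmr_threshold` (default 0.3, separating the Beta(1,9) hypomethylated
regime from the Beta(8,2) background with essentially no overlap); low
bins are merged across gaps first and a merged region must contain ≥
`hmr_min_bins` (default 3) low bins — merging before the minimum-bin
filter prevents a single noisy edge bin from clipping a region's
boundary. Cross-sample consistency takes maximal intervals covered by ≥
`min_samples` per-sample HMRs (default: all samples, the "consistent at
all ages" reading) and additionally requires a reciprocal overlap of ≥
0.5 with a supporting HMR in each counted sample, so a long consensus
cannot be stitched from barely-touching fragments. Uncovered bins are
treated as signal 0 (with a warning) in enrichment calling and as
not-hypomethylated in HMR calling, keeping support fractions comparable
across tracks with missing data.

Exact reproduction of the published S/A/B/H boundaries from public
tracks is out of scope by design: those boundaries were identified
visually with unstated thresholds. The package instead ships the printed
relative coordinates as fixtures and proves property-level agreement
(containments, overlap lengths, TSS spanning) plus parameter-recovery
benchmarks on synthetic truth.

# Co-localization

Interval arithmetic is done on half-open base intervals in a single
coordinate space (TSS-relative sets are converted to genomic via the
anchor when mixed). Overlap and Jaccard matrices, containment reports
(`contained`/`partial`/`none`) and labelled set intersections are all
validated against a quadratic brute-force scan; claims of the form "most
fragments intersect" are reported as computed counts and fractions,
never asserted constants.

# Determinism and numerical choices

All randomness flows from a single integer seed per generator call (the
global RNG state is saved and restored); CLI runs with identical
arguments and seed produce identical output trees. Alignment scores are
integer-valued in double precision, so DP ties are exact. Quantiles use
R's default type-7 definition. The kb fixtures are expanded by ×1000
before arithmetic, avoiding fractional-kb rounding. Degenerate inputs
(empty regions, bins larger than the region, empty fragment sets, empty
proteins, fractions outside [0,1]) raise immediate errors rather than
propagating.

# Known limitations

- The packaged sequences and domain coordinates are synthetic stand-ins;
  categorical table reproduction demonstrates the classifier on a
  faithful architecture, not on database residues.
- The novel-fragment locator is ungapped; a fragment whose genomic
  source contains an indel relative to the query would be reported at
  reduced identity or missed.
- The segment caller assumes roughly exchangeable tracks; a single
  much-deeper track is handled by the per-track quantile, but correlated
  artefacts across tracks (e.g. blacklist regions) would be called.
- Cross-assembly support is re-anchoring at printed TSS values only;
  there is no general liftover.
- Problem sizes in the shipped tests and the acceptance script (150-kb
  region, 200-bp bins, 20 replicate seeds, ≤ 8-residue oracle pairs) are
  the package's chosen benchmark scale; all callers accept larger
  inputs.
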