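---
title: "riboloop: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboloop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and conventions behind riboloop's
post-processing of bacterial ribosome profiling (Ribo-seq) data: what each
stage computes, the assumptions it makes, the parameters that matter, and
the design choices taken where the field's practice is not unique. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinates and circular chromosomes

All internal coordinates are 0-based half-open `[start, end)`; conversions
to 1-based conventions (GFF3 inclusive, wiggle positions) happen only at
file boundaries. Bacterial chromosomes are circular, and genes or reads that
cross the replication origin are a standing failure mode for tooling built
for linear genomes — they surface as negative coordinates or records with
`end < start`. riboloop's answer is a single canonical representation:
origin-spanning features are *unwrapped*, with `start ∈ [0, L)` and
`end > L`, so `end − start` is always the feature length and every position
is recovered with one modular reduction (`pos mod L`). Both wrapped
(`end < start`) and negative-coordinate encodings are normalised into this
form on input (`unwrap_interval()`), and GFF3 output emits one record with
wrapped 1-based coordinates plus an `origin_spanning=true` attribute. The
wrapped-output choice is this package's decision — the convention used by
existing pipelines is not standardised — and is symmetric: reading our own
output restores the unwrapped form exactly, a property tested on 1000
randomised features.

Reads are treated as ungapped blocks (reference span = read length).
Bacterial footprints are short and unspliced; alignments whose CIGAR
contains indels use the reference span, with a warning. On circular contigs
the synthetic SAM writer keeps origin-spanning alignments unwrapped (POS
near the contig end, CIGAR running past it); `read_alignments()` accepts
this and errors on linear contigs.

## Filtering

Multimapped reads (SAM `NH > 1`; `MAPQ == 0` heuristic when the tag is
absent, warned) are removed first, then any read overlapping an annotated
rRNA feature by ≥ 1 nt on *either* strand — contamination is discarded
regardless of annotated orientation, and the 1 nt threshold is deliberately
aggressive since rRNA loci dwarf footprints. Whether tRNA reads should also
be dropped is left to the `rrna_types` option (default `rRNA` only). The
`FilterReport` enforces exact conservation
(`input = multimapped + rRNA + retained`), and both filters are idempotent.

## Coverage tracks

Single-nucleotide mapping reduces each footprint to one informative
position: the 5′ end (default diagnostic for bacterial data), the 3′ end,
or the center. On the reverse strand the biological 5′ end is the maximal
coordinate (`end − 1`). The center of an even-length read is ambiguous; the
*left* of the two central positions is used, a deterministic tie-break. In
these modes a raw track's total equals the contributing read count exactly —
the conservation law the acceptance tests check against a position-stepping
oracle. Per-million scaling (`cpm`) divides by the number of *retained*
reads per library: post-filter reads are the set every downstream stage
sees, which makes track heights comparable with the count-based statistics.
Minus-strand tracks are written as non-negative values in separate `.rev`
files; negation is a display concern. Only text formats (wiggle, bedGraph)
are produced.

## Metagene profiling

For each annotated CDS start (first nucleotide of the start codon; on the
minus strand `end − 1`), reads anchored within
`[-window_upstream, window_downstream)` of the start are tallied into a
read-length × offset matrix. Defaults of 50 nt on each side bracket
bacterial footprint lengths (20–45 nt default range) with room for
initiation-proximal signal; both are options. The anchor is the 5′ end by
default — the convention that makes initiation peaks sharpest in bacterial
data — with 3′/center exposed as options. Genes whose full window would
cross the edge of a linear contig are excluded (and counted in the
diagnostics); on circular contigs windows wrap. A read landing in k
overlapping gene windows contributes k increments: the profile is an
aggregate diagnostic, not a per-gene quantity, so no ambiguity resolution is
attempted. The frame summary groups coding-side offsets by `offset mod 3`
per read length; it is the package's operational measure of
three-nucleotide periodicity and of which footprint lengths carry frame
information. A row-normalised profile variant (each read-length row scaled
to sum 1) is written alongside the raw counts for cross-length comparison.

## ORF merging and novelty

Predictions from external bacterial ORF callers are consumed as GFF3 and
merged with the annotation under an *exact-identity* rule: two records are
the same ORF iff (contig, strand, start, stop) match after wrap
normalisation. Same-stop/different-start calls remain separate records —
start-site heterogeneity is biologically meaningful in Ribo-seq and
collapsing to the longest isoform would erase it; this exact-match semantics
is a package decision, not a community standard. Novelty means no annotated
*CDS* shares the key (ncRNA or pseudogene records do not rescue an ORF from
novelty). Evidence entries `(tool, condition, replicate, score)` accumulate
per key, are deduplicated and canonically sorted, which makes merging
idempotent and invariant under permutation of the prediction sets. Output
order is (contig, wrapped start, strand, end) — the trailing `end` is a
tie-break for isoforms sharing a start.

## Quantification and translation efficiency

Counting is strand-specific with unique assignment: a read overlapping ≥ 1
nt of exactly one ORF counts for it; a read overlapping two or more ORFs is
discarded as ambiguous and reported, so
`assigned + ambiguous + unassigned = retained` holds exactly per library.
RPKM (`count · 10⁹ / (length · library size)`) and TPM (rates normalised to
10⁶) are both provided and labelled explicitly, since "normalized counts"
alone is underspecified; ORF length includes the stop codon, matching GFF3
CDS extents. Translation efficiency per condition is
`mean(RPKM_RIBO) / mean(RPKM_RNA)` across replicates — replicate-weighted
rather than pooled-count, so a deep replicate cannot dominate — and is `NA`
when the RNA mean is zero. A condition with RIBO but no RNA libraries is a
validation error before any computation.

## The simulator: a stated world

`simulation_spec()` defaults describe the world the tests assume: an 8 kb
circular chromosome; six ORFs of 120–300 nt placed without overlap and with
≥ 60 nt gaps (so a footprint can never straddle two ORFs and planted per-ORF
counts are exactly recoverable); the first ORF spans the origin; one ORF is
withheld from the annotation to exercise novelty calling; one rRNA locus;
footprints of 26–30 nt peaking at 28; a 5× start-codon 5′-density peak; 90%
in-frame placement; 10% rRNA contamination; 5% multimappers (NH = 2, drawn
among ORF reads); uniform RNA-seq coverage along each ORF. Everything flows
through one pseudo-random stream seeded from `spec$seed`, making FASTA,
GFF3 and SAM outputs byte-reproducible.

One modelling point deserves emphasis. TE is a ratio of per-million
normalised quantities and is therefore *compositional*: if RIBO depth per
ORF is proportional to planted TE while RNA depth is flat, library-size
normalisation rescales every estimate by `n / Σtе`. So that planted values
are recovered on their stated absolute scale, the generator pads libraries
with intergenic background reads to equal retained depth
(`equalize_depth = TRUE`). This mimics the real situation in which the
non-ORF fraction of a library buffers compositional shifts; it is a property
of the stated world, not a tuning knob, and it is switched off where a
fixture's total read count is itself specified.

What the simulator does **not** model: sequencing errors, quality scores,
adapter remnants, positional coverage heterogeneity beyond the start peak,
operon structure, or overlapping genes. A green test therefore establishes
the correctness of the *computations* (coordinate arithmetic, conservation
laws, estimator identities) — not robustness to the full messiness of real
libraries.

## Numerical and degenerate-input choices

- Track values are printed as integers when integral, otherwise with 10
  significant digits; raw-track file round trips are exact.
- Overview-table floats are printed with 4 significant digits; missing
  values are the literal `NA`.
- Zero-signal metagene rows yield all-zero frame fractions (not NaN).
- An all-zero count vector yields all-zero TPM (the 10⁶ column-sum property
  applies only when signal exists).
- Empty read sets, empty start lists, empty prediction sets and header-only
  tables are all defined outputs, not errors; an empty *library* (size 0)
  is an error wherever it would be a denominator.
- `tabulate()`-based accumulation keeps coverage exact integer arithmetic
  until normalisation.

## Pipeline and reproducibility

`run_all()` executes filter → coverage → metagene → merge → quantify →
report sequentially in-process; no workflow engine is used, and the
pipeline itself draws no random numbers, so fixed inputs give byte-identical
tabular and track outputs (checked in the acceptance suite). A
`manifest.json` records inputs, parameters, package version and md5
checksums of every output. The run configuration is JSON rather than YAML —
no YAML parser is available in the supported dependency set, and the
structure is identical.

## Known limitations

- No P-site offset calibration: single-nucleotide tracks use uncorrected
  read ends, as appropriate for data where no offset model has been fitted.
- No stop-codon metagene and no per-gene pause statistics.
- Differential expression is consumed (as TSV with `log2FC`/`padj`), never
  computed.
- BAM input requires Rsamtools; the package's own I/O is plain-text SAM.
- Counting offers only unique assignment; fractional or EM-based
  multi-overlap assignment is out of scope.
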