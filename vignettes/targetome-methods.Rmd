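---
title: "Methods: deletion-based CLIP targetome and miRNA transcript analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deletion-based CLIP targetome and miRNA transcript analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetome)
```

## The problem

An RNA-binding protein (RBP) captured by HITS-CLIP leaves two kinds of
evidence in sequencing data. First, UV crosslinking perturbs reverse
transcription so that reads covering a contact site frequently carry a
deletion at the crosslinked nucleotide; the genomic positions of these
deletions are direct, near-nucleotide-resolution binding evidence. Second,
the distribution of CLIP tags across transcript regions, miRNA precursors
and splice-site neighborhoods characterizes *what* the protein binds:
mRNA 3'-UTRs, primary miRNA transcripts, intronic positions near splice
sites, and so on. For an RBP implicated in miRNA biogenesis, RNA-seq and
small-RNA-seq from knockdown versus control cells then quantify the
downstream consequences: changes in miRNA primary-transcript levels,
mature miRNA levels, mirtron splicing (intron retention) and 3'-UTR
isoform choice.

`targetome` implements this analysis stack as a reusable, fully tested
pipeline, together with a synthetic-data generator that plants every
signal the analyses are supposed to detect, so each stage can be validated
without any external download.

## Coordinate model

All internal interval arithmetic uses the 1-based, closed-interval
convention of `GenomicRanges`/`IRanges`, the substrate of the whole
R/Bioconductor genomics stack this package builds on. GTF/GFF3 (1-based)
and BED (0-based, half-open) conversions are delegated to `rtracklayer`;
SAM parsing keeps the SAM 1-based `POS`. An earlier design sketch called
for 0-based half-open internal coordinates; we deviated because re-basing
against the grain of the host ecosystem is itself a classic source of
off-by-one errors, which the chosen convention avoids by never converting
except at (library-managed) file boundaries.

## Region model

Gene models are flattened into a strand-specific disjoint *region index*
with labels `5'UTR`, `CDS`, `3'UTR`, `intron`; everything else is
`intergenic`. When transcripts overlap, a base takes the highest-priority
label under `CDS > 3'UTR > 5'UTR > intron > intergenic` — the source
method did not specify a rule, and a fixed precedence makes the partition
deterministic and testable (the per-strand labelled pieces plus the
intergenic complement tile each chromosome exactly). Reads are labelled by
the majority of their aligned bases, ties resolved by the same precedence.
Only coding transcripts contribute to the index: the five-label vocabulary
is mRNA-centric, and the analyses that consume it are mRNA analyses.
Reads count only toward same-strand features throughout, matching
strand-directional library chemistry.

## Crosslink sites

Every base covered by a `D` CIGAR segment is a *deletion residue*;
distinct `(chromosome, strand, position)` triples collapse into unique
*crosslinked sites* with a residue count. Both numbers are reported
separately because their roles differ (sites for positional histograms,
residues for weighting); a multi-nucleotide deletion contributes one
residue per deleted base by default, or a single residue at its first base
under `mode = "event_start"`. Insertions and mismatches are parsed but not
used for site calling. Site calling is order-independent and
`n_residues >= n_sites` always.

Sequence context is profiled as base fractions at offsets −flank..+flank
(default 100 nt) around sites, strand-oriented (minus-strand windows
reverse-complemented), with edge sites dropped and counted.

## Structure potential

Local secondary-structure potential is proxied by a maximum-base-pairing
(Nussinov-style) dynamic program over canonical pairs (AU, GC, GU wobble)
with a minimum hairpin loop of 3 nt, implemented in C++ for the O(n³)
window folds. The per-offset *pairing fraction* is the share of windows in
which that position is paired in the computed optimum. A thermodynamic
folder would be more faithful but would add a heavy external dependency
for what the analysis uses only as a relative signal; the DP is exact for
its own objective (verified against exhaustive enumeration for n ≤ 12).

Traceback ties are resolved toward the *most distant* admissible partner.
We first tried the nearest/leftmost partner; on perfect stems with
enclosed loops that rule happily trades long-range stem pairs for
equal-score pairings into the loop (measured stem/loop pairing 0.90/0.35
on generator hairpins), destroying the stem-versus-loop contrast that the
method's own sanity check relies on. Preferring the distant partner mimics
the stacking preference of real duplexes and yields stem/loop = 1.0/0.0,
while remaining fully deterministic.

## Metagene and terciles

Coverage along each selected transcript's 5'-UTR, CDS and 3'-UTR is
rescaled to 100 bins per region in transcript orientation, summed over
transcripts, and the 300-bin curve normalized to unit area ("normalized
sequencing depth" is otherwise underdetermined; unit area makes replicate
curves comparable). An optional per-transcript normalization (each
transcript's curve scaled to unit mass before summation) is available and
off by default. Transcripts are ranked by 3'-UTR length (ties by id) and
split into terciles with the remainder assigned to the *short* group —
the only rule consistent with the published 10,872/10,872/10,873 split of
32,617 transcripts.

## miRNA read categories and form calls

Reads overlapping a hairpin ± 100 nt window by ≥ 1 nt (same strand) are
classified by the first matching rule: **I** within the mature miRNA with
at most 1 nt total excess (a per-end interpretation is available via
`excess_per_end`); **II** inside the hairpin with ≥ 1 nt mature overlap;
**III** inside the hairpin without mature overlap; **IV** crossing a
hairpin boundary; **V** entirely outside the hairpin within the window.
First-match-wins makes the partition deterministic where the verbal
definitions overlap at boundaries. Forms are called per miRNA at a
five-read minimum: mature from I, pre from II+III, pri from IV+V; raising
the threshold can only remove forms (tested by fuzzing thresholds 1–10).
A read near two hairpins is evaluated against each independently; form
calls are per-miRNA, so no within-miRNA double counting arises. Hairpin
midpoints for meta-profiles are `start + floor(width/2)` in hairpin
orientation.

## miRNA transcript quantification

The "whole level" of a miRNA transcript is RNA-seq read density in the
hairpin ± 200 nt window: reads overlapping by ≥ 1 nt on the same strand,
excluding reads fully contained in the pre-miRNA (absent from a
size-selected library), normalized per million library reads per kilobase
of window so windows of unequal hairpin length compare. Differential
calls use strict > 1.5-fold with, for mature miRNAs, a TPM floor of 1.5
applied to the larger of the two conditions (the source text does not say
which sample the floor refers to; max is the permissive reading, and
min/mean are available). Transcript-side fold changes add a 0.5-read
pseudocount before ratio formation to avoid division by zero.

## Splice-site proximity

Unique introns (collapsed across transcripts sharing them) define two
windows: 200 nt into the intron from the 5' splice site and from the 3'
splice site, with 1-based offsets. Each intronic crosslinked site is
assigned to the *nearer* junction only (ties to the 5' side), so short
introns never double-count a position; each unique genomic position
counts once per histogram, with residue counts accumulated separately.
Junction base composition keeps only ± 100 nt windows whose intronic half
contains a site, and reports exonic and intronic halves separately in
transcript orientation.

## Intron retention and isoform ratios

Exclusion evidence for an intron is a read whose `N` segment skips exactly
that intron; retention evidence is ≥ 6 nt of aligned sequence in the
intron interior without such a skip (the 6-nt floor keeps
junction-adjacent exonic reads out; the source measured these isoforms by
RT-PCR, so the read-level proxy is this package's own definition).
`PIR = 100 · retention / (retention + exclusion)`, undefined (NA) when
both counts are zero. Whole-level changes across conditions are ratios of
per-million-normalized evidence totals. The long-isoform ratio compares
mean read depth over a region unique to the long 3'-UTR isoform with the
depth over the shared region; short-isoform evidence is the difference,
floored at zero, so uniform coverage reads as "all long".

## The synthetic world

`simulation_config()` fixes a small but structurally complete world:

* two chromosomes (260 + 170 kb), 30 coding genes with 3–5 exons,
  intron widths 700–1,500 nt, 5'-UTRs of 80–200 nt and 3'-UTR lengths
  log-normally spread (60–2,500 nt) with a handful forced long to host
  3'-UTR miRNAs;
* ten 78-nt hairpins (30 nt arms, 18 nt loop) split 4/3/3 across
  intronic, 3'-UTR and intergenic placements. Arms are exact reverse
  complements written into the genome; the loop is drawn from {A,C} only,
  an alphabet with no canonical partner, so folding shows a clean
  stem-versus-loop contrast by construction;
* binding sites in 3'-UTRs with placement probability proportional to
  3'-UTR length (exponent configurable), and intronic sites at a
  configurable offset upstream of the 3' splice site
  (mean 50 nt, the positional signal the splice-distance histogram is
  meant to recover);
* CLIP reads of 25–40 nt: around sites (1-nt deletion written into the
  CIGAR at the planted position with probability 0.3, the read always
  retained within a single labelled region so its true label is known),
  hairpin-window reads constructed to satisfy exactly one category
  (pri-dominant mix, as observed for this class of RBP), and background
  on transcribed regions, split over three replicate libraries;
* RNA-seq (100 nt) where window read counts are Poisson around
  `level × reads_per_level`, intron-hosted miRNAs couple window reads
  (retention isoforms) with junction-spanning exclusion reads via the
  planted retention fraction, other introns receive `n_informative`
  reads split binomially by their planted PIR, and exonic gene background
  scales with planted gene levels;
* small-RNA reads with lengths peaked at 21–25 nt for miRNAs plus a
  condition-invariant piRNA-like background class (26–31 nt). The
  background is not decoration: without it, within-library TPM is purely
  compositional and a global miRNA knockdown would be mathematically
  invisible, which contradicts both the real assay (where non-miRNA small
  RNAs anchor the denominator) and the recovery behavior the analysis is
  designed to show;
* knockdown multiplies each miRNA's level by a fold drawn from
  {0.25, 0.4, 0.5, 1, 2} with down-shifted weights, and raises mirtron
  retention from 0.15 to 0.55 — the direction of effect of a helicase
  knockdown that suppresses miRNA output and biases splicing toward
  retention.

Everything is driven by one seed (stage seeds are derived offsets), and
reruns are byte-identical down to the written files. What a green test
does *not* establish: the generator has no sequencing errors, adapter
artifacts, PCR duplicates, mappability gaps, overlapping genes,
non-coding transcripts or isoform diversity; genomic percentages observed
on real libraries (e.g. fractions of genic tags or repeat overlap) are
properties of real data, not of these algorithms, and are deliberately not
asserted.

## Numerical and degenerate-input choices

Base-fraction columns renormalize over called bases, so rare `N`s cannot
break the sum-to-one invariant. Profiles normalize to unit area only when
total coverage is positive; empty inputs give zero profiles with a
warning where the operation is well-defined (e.g. hairpin meta-profiles)
and errors where it is not (e.g. composition of an empty site set). PIR
and transcript-change ratios report NA, not zero, when their denominators
vanish. Fragment counting uses ≥ 1 exonic-nt overlap, once per transcript
per fragment — a documented simplification that replaces isoform
deconvolution, with FPKM's per-million denominator being the fragments
assigned to at least one feature in that library.

## Known limitations

Maximum-base-pairing is a proxy, not thermodynamics; CIMS-style
permutation significance for sites is out of scope (sites are called, not
scored); expression is transcript-level counting, not an EM deconvolution;
mirtron membership is an input annotation, not a prediction. The CLI
exposes the simulate and full-run entry points; individual stages are the
R functions documented here.
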