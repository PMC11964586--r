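---
title: "Methods: linked isoform structure and expression figures"
author: "TranscriptViz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked isoform structure and expression figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TranscriptViz)
```

# The problem and the model

A gene's isoforms share a locus but differ in exon composition, and their
relative expression often differs between biological groups. The figure
this package produces answers both questions at once: one row per
displayed isoform, a structure panel on the left (exon boxes, taller CDS
boxes, intron lines with strand arrows) and one or more expression panels
on the right (grouped boxplots with all sample points overlaid), all rows
vertically aligned across panels.

Three computations carry the scientific content; everything else is
plumbing around them.

## Normalization

For counts $x_{ts}$ (transcript $t$, sample $s$):

$$\mathrm{CPM}_{ts} = \frac{x_{ts}}{\sum_{t'} x_{t's}} \times 10^6, \qquad
\mathrm{RA}_{ts} = \frac{x_{ts}}{\sum_{t' \in g(t)} x_{t's}} \times 100,$$

where $g(t)$ is the gene of $t$. The CPM library size is the column sum of
*the supplied matrix*. This is a deliberate, consequential choice: if the
matrix is subset to one gene before normalizing, the library size — and
every CPM value — changes. The pipeline therefore always normalizes before
gene filtering, and the stage log records that order. Relative abundance is
length-free by construction; the package deliberately omits TPM/FPKM
(length-aware) normalization, which answers a different question.

Zero denominators (a sample with zero total; a gene with zero counts in a
sample) yield 0, not NaN, with a warning. Figures stay renderable for
sparse data, and a 0% share of a silent gene is the least misleading value
to draw. Both conservation laws — CPM columns summing to $10^6$, per-gene
abundances summing to 100 where totals are positive — are enforced by
property tests, at relative tolerance $10^{-6}$ and absolute tolerance
$10^{-9}$ respectively, far above floating-point noise but strict enough to
catch any indexing error.

## Structure annotation

Exons are numbered $1..n$ in transcription order: ascending genomic start
on `+`, descending on `-`. A CDS record inherits the number of the exon
containing it; a CDS contained in no exon is a validation error, not a
warning, because it indicates a corrupt annotation. Introns are derived as
`(previous exon end + 1, next exon start − 1)` from start-sorted exons;
abutting exons produce no intron, overlapping exons within one transcript
are an error naming the transcript. Two invariants pin these down: exon
plus intron lengths tile the transcript span exactly, and flipping the
strand reverses the numbering permutation exactly.

Strand handling motivates a strict parsing rule: GTF records with strand
`.` or `?` are rejected at parse time. Numbering and intron arrow direction
are strand-dependent, and a silent default would mislabel half the display.

## Long-intron rescaling

Introns are commonly orders of magnitude longer than exons; drawn to scale,
exon structure collapses into slivers. The package compresses intronic
space through a single piecewise-linear, strictly increasing map from
genomic to display coordinates, built per plotted locus:

1. take the union of exon intervals across *all* displayed transcripts;
2. regions covered by that union keep their genomic length;
3. each uncovered gap is given display length `min(gap, cap)`, interior
   positions interpolating linearly.

Building the map from the exon union — never per transcript — is the
critical unstated requirement of multi-isoform display: every transcript is
drawn through the same axis, so shared exons land at identical display
positions in every row. An exon of one isoform inside another isoform's
long intron keeps its region covered; only the flanking uncovered sub-gaps
compress.

The compression rule is fixed-cap rather than proportional: gaps at or
below `cap` are untouched, longer gaps compress to exactly `cap`. Among the
rules satisfying the shared-axis requirement it is the simplest, it keeps
short introns to scale, and it makes the identity limit obvious (`cap` at
least the longest gap leaves every coordinate unchanged). The default
`cap = 100` bp-equivalent display units keeps a compressed gap visually
comparable to a typical exon. `cap` must be a whole number: segment
boundaries then stay integral, and every feature boundary (always adjacent
to a covered base) maps to an integer display coordinate, so rescaled
annotations remain ordinary integer ranges.

Correctness is checked against a deliberately naive oracle: walk the locus
base by base, advance display by 1 on covered bases and by
`min(gap, cap)/gap` inside gaps. Segment map and oracle must agree exactly
at every exon/CDS/intron boundary. The validation sweep uses 200 random
loci of up to 50 kb with 1–4 transcripts each — large enough to contain
every interleaving pattern the map distinguishes, small enough that the
per-base walk stays trivial.

# Figure semantics

* **Rows.** `rankAndSelect` orders transcripts by `reducer(metric)`
  descending (default: mean CPM), ties broken by transcript ID in C-locale
  lexicographic order so ranking is reproducible across platforms; the top
  N (default 5) become the shared row order, top row first.
* **Boxes.** Quartiles use the linear-interpolation (type-7) rule — the
  convention the package documents rather than inherits silently, since
  quartile definitions differ across software. Fences sit at
  `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR`; whiskers end at the most extreme data
  values inside the fences, falling back to the quartile when no point lies
  beyond it; points outside are outliers. All raw points are drawn, with
  deterministic seeded jitter, so with the group sizes this package targets
  (often n = 4 per group) no summary hides the data.
* **Heights.** CDS boxes are exactly twice exon height. The ratio is fixed
  rather than configurable-by-default: it is the one visual encoding the
  figure's interpretation depends on.
* **Hover.** Every exon/CDS payload carries transcript, chromosome,
  genomic start, genomic end, genomic length (`end − start + 1`) and exon
  number. Lengths are always genomic, never display lengths — the
  rescaling is a drawing device and must not leak into reported numbers.
* **Arrows.** Strand direction is marked on intron lines at regular display
  intervals (default 400 units); compressed introns at least 20 display
  units long get a single midpoint marker so direction is never absent
  where there is room to show it. Arrows are confined to introns; inside
  exons they would collide with the boxes.
* **Legend.** One entry per metadata group; clicking it toggles that
  group's boxes and points across *all* expression panels at once. Colors
  come from a qualitative palette indexed by group order in the metadata.

## Export

The figure is first assembled as a renderer-independent `FigureSpec`
(shapes, statistics, payloads, groups); exporters then translate it. The
interactive exporter writes SVG with a small embedded JavaScript runtime
(tooltips, legend toggling, wheel zoom, drag pan) authored inside the
package. Writing the renderer in-package keeps the output fully
self-contained — one file, no network, no external runtime — and makes
exports byte-deterministic, which turns "the figure did not change" into a
checksum comparison in tests and pipelines. The cost is accepting a small
feature set compared to a charting library; the interactions implemented
are exactly those the figure's reading requires. Static export shares the
same geometry: SVG from the same writer (also byte-deterministic), PNG/PDF
through the standard R graphics devices.

# The fixture generator

`generateFixture` produces the study-shaped dataset the tests and examples
run on: by default 3 genes on alternating strands, 2–8 transcripts per
gene with the first gene guaranteed at least 6 (so top-5 selection is a
real choice), exons of 50–300 bp, gaps of 60–900 bp plus one guaranteed
5000 bp gap per gene (50 times the default cap, so rescaling is always
exercised), 70% of transcripts coding with CDS trimmed inside their exons,
and eight samples in two groups of four. Counts are negative-binomial
(dispersion 0.3, per-transcript means log-uniform on 20–2000) with a
per-gene group log2 fold-change uniform on ±1.5 — group-structured
expression of the kind a small case/control isoform study shows. Group
sizes of four reflect the small-cohort setting this figure type is
typically used in.

Each transcript's exons are drawn from the gene's union-exon chain, with
the first transcript using the full chain. That makes the generator's truth
record — expected ranking from the realized counts, intron coordinates, and
gap-map segments derived from the known chain layout — computable by
bookkeeping, independent of the interval algebra under test.

What the fixtures do *not* emulate: alternative 5'/3' splice sites within
an exon (all isoforms share exact union-exon boundaries), overlapping genes
on one locus, unstranded or multi-chromosome transcripts, sequencing-depth
imbalance between samples, and any read-level error structure. Passing
tests therefore demonstrate the correctness of the coordinate arithmetic,
normalization, statistics and rendering contracts — not robustness to every
annotation pathology in the wild. Real ENSEMBL-style GTFs differ mainly by
carrying more attributes (ignored) and UTR/start/stop rows (filtered by
`keepKinds`).

# Numerical and edge-case decisions

* Coordinates are 1-based inclusive everywhere (the GTF convention),
  display coordinates included; length is always `end − start + 1`.
  Keeping one convention end-to-end avoids the classic off-by-one churn at
  format boundaries.
* The GTF parser accepts both quoted (ENSEMBL) and unquoted attribute
  dialects in its default lenient mode; strict mode is available when
  provenance matters. Unknown attribute keys are ignored, not stored.
  Missing `gene_name`/`transcript_name` fall back to the IDs so downstream
  labels are never empty; a source column of `.` reads as missing.
* Duplicate identical records are dropped with a warning (they are
  redundant, not contradictory); genuinely conflicting records — one
  transcript on two strands or two chromosomes — are validity errors.
* Degenerate loci are well-defined: a single-exon, single-transcript gene
  yields an identity gap map and zero introns; constant expression yields a
  zero-width box with no outliers; an empty group yields an empty box with
  a warning rather than an error.
* Ranking `topN` beyond the number of available transcripts returns all of
  them with a warning — the caller asked for "up to N", and failing would
  make batch loops brittle.
* Batch mode treats per-gene failures as data problems, not program
  failures: the gene is logged, skipped and recorded in the manifest.

# Scope and limitations

The package draws transcript models and expression summaries; it does not
compute differential expression or isoform switching (pair it with edgeR,
DESeq2 or satuRn for inference), does not draw per-base coverage, splice
graphs, or protein domains, and does not parse GFF3 or write BED. The
rescaled axis is intentionally non-linear; the hover payloads carry the
genomic truth, and any measurement should be read from them, never from
on-screen distances. Validation problem sizes (200 loci for the map oracle,
100 matrices for conservation, 1000 samples for box statistics, a 50-gene
batch) were chosen as the smallest sweeps that exhaust the distinct
combinatorial cases each property has; the properties themselves are
size-free.
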