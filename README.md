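# TranscriptViz

Linked visualization of RNA isoform structure and expression for R.

Alternative splicing lets a single gene produce many RNA isoforms, and
isoform-level results are hard to interpret from either a structure track or
an expression table alone: you need both in one view, aligned transcript by
transcript. TranscriptViz is for transcriptomics researchers (bulk or
single-cell, short- or long-read) who have a GTF annotation and a
transcript-level counts matrix and want a programmable, reproducible figure
showing which isoforms of a gene are expressed, how strongly, and how their
exon/CDS structures differ.

## What it computes

Given counts `x(t, s)` for transcript `t` in sample `s`:

* **Counts per million**: `CPM(t, s) = x(t, s) / Σ_t' x(t', s) × 10⁶`, the
  library size being the column sum over the supplied matrix. Because
  subsetting first would change the library size, the pipeline always
  normalizes before gene filtering.
* **Relative transcript abundance**: for gene `g` containing `t`,
  `RA(t, s) = x(t, s) / Σ_{t' ∈ g} x(t', s) × 100` — each isoform's
  percentage share of its gene, per sample.
* **Isoform selection**: transcripts ranked by `reducer(metric)` across
  samples (mean/median/sum of counts, CPM or relative abundance), ties
  broken lexicographically; the top N are displayed.
* **Structure annotation**: strand-aware exon numbering (1..n in
  transcription order, reversed on the minus strand; CDS inherit their
  containing exon's number) and intron derivation
  (`intron = (prev_exon_end + 1, next_exon_start − 1)`).
* **Long-intron rescaling**: a piecewise-linear genomic→display map built
  from the union of exons across all displayed transcripts. Covered regions
  keep their genomic length; each uncovered gap is compressed to at most
  `cap` display units (default 100 bp-equivalents). One shared map keeps
  every isoform aligned on a single axis while exons stay to scale.
* **Grouped box statistics**: per (transcript, group) median, type-7
  quartiles, Tukey fences at `Q1 − 1.5·IQR` / `Q3 + 1.5·IQR`, whiskers at
  the most extreme data values inside the fences, outliers beyond them, and
  all raw points retained for overlay.

The result is a renderer-independent `FigureSpec` exported as
self-contained interactive HTML (hover details per exon/intron/box/point,
one legend entry per sample group that toggles that group across all
panels, zoom and pan) or as static SVG/PNG/PDF. Identical inputs and seed
give byte-identical output files.

## Worked example

The package ships a deterministic fixture generator, so the example is
fully reproducible:

```r
library(TranscriptViz)

fx  <- generateFixture(fixtureConfig(seed = 7), "fixture")
ann <- readGTF(fx$gtf)
ann
#> FeatureTable with 130 records (3 genes, 15 transcripts)
#>   kinds: CDS=34, exon=96

expr <- joinMetadata(readExpression(fx$counts), readSampleMetadata(fx$metadata))
expr <- normalizeCPM(expr)
expr <- normalizeRelativeAbundance(expr, transcriptGeneMap(ann)[rownames(expr)])
expr
#> TranscriptExpression: 15 transcripts x 8 samples
#>   assays: counts, cpm, relative_abundance
#>   gene mapping: 3 genes
#>   sample metadata: condition

cfg <- runConfig(gtf = fx$gtf, counts = fx$counts, metadata = fx$metadata,
                 gene = "GENE001", topN = 5, out = "fig.html")
runPlot(cfg)
#> [...] [filter-gene] gene 'GENE001': 37 records, 6 transcripts
#> [...] [rank-select] top 5 by mean(cpm): GENE001.T05, GENE001.T01, GENE001.T04,
#>                    GENE001.T03, GENE001.T02
#> [...] [gap-map] 9 segments, cap 100
#> [...] [export] wrote fig.html
```

The log shows the pipeline at work: the focal gene has 6 isoforms, the five
with highest mean CPM are kept (in rank order, top row first), and the
locus is compressed into 9 alternating covered/gap segments with gaps
capped at 100 display units. `fig.html` opens in any browser with no
network access: the left panel shows each isoform's exon boxes (CDS drawn
twice as tall), intron lines with strand arrows, and per-exon hover
payloads (chromosome, genomic start/end, genomic length, exon number,
transcript); the right panel shows case/control boxplots of CPM with
jittered sample points, toggled per group from the legend.

A command-line wrapper with `plot`, `batch`, `validate`, `simulate` and
`stats` subcommands is installed at
`system.file("cli", "transcriptviz", package = "TranscriptViz")`.

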