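Package: TranscriptViz
Title: Linked Visualization of RNA Isoform Structure and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Renders RNA isoform structures and per-isoform expression side
    by side. Ingests gene annotation in GTF format and transcript-level
    expression matrices, joins sample metadata, computes counts-per-million
    and relative transcript abundance, selects and orders isoforms by
    expression, derives introns and strand-aware exon numbering, rescales
    long intronic regions through a piecewise-linear coordinate map shared
    across all displayed transcripts, and assembles a linked
    structure/expression figure exported as self-contained interactive HTML
    or as static SVG/PNG/PDF. Includes a deterministic synthetic-data
    generator for annotation, counts and metadata, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    arrow,
    readxl,
    rtracklayer,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'TranscriptViz-package.R'
    'accessors.R'
    'annotation-io.R'
    'rendering.R'
    'figure-export.R'
    'transform.R'
    'cli.R'
    'expression-io.R'
    'fixtures.R'
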