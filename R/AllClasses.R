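#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

FEATURE_KINDS <- c("gene", "transcript", "exon", "CDS", "intron")

#' FeatureTable: long-form genomic feature annotation
#'
#' An ordered collection of gene/transcript/exon/CDS/intron records held as a
#' [GenomicRanges::GRanges] with the metadata columns `type`, `source`,
#' `gene_id`, `gene_name`, `transcript_id`, `transcript_name`,
#' `transcript_biotype` and `exon_number`.  Coordinates are 1-based inclusive
#' (the GTF convention) everywhere, display coordinates included, so interval
#' length is always `end - start + 1`.
#'
#' Validity requires: strand strictly `+` or `-`; exon and CDS records carry
#' non-empty `gene_id` and `transcript_id`; all records of one transcript
#' share a single seqname and strand; no duplicated
#' `(transcript_id, type, start, end)` tuples; and any transcript with CDS
#' records also has exon records.
#'
#' @slot records A `GRanges` of feature records, order-preserving.
#' @slot provenance A list describing where the records came from (source
#'   path, parse options); purely informational.
#' @seealso [readGTF()], [writeGTF()], [featureRecords()], [featureFrame()]
#' @export
setClass("FeatureTable",
  representation(records = "GRanges", provenance = "list"),
  prototype(provenance = list())
)

REQUIRED_MCOLS <- c(
  "type", "source", "gene_id", "gene_name", "transcript_id",
  "transcript_name", "transcript_biotype", "exon_number"
)

setValidity("FeatureTable", function(object) {
  gr <- object@records
  msgs <- character()
  missing_cols <- setdiff(REQUIRED_MCOLS, colnames(mcols(gr)))
  if (length(missing_cols) > 0) {
    return(paste("missing metadata columns:", paste(missing_cols, collapse = ", ")))
  }
  if (length(gr) == 0) return(TRUE)
  m <- mcols(gr)
  if (!all(m$type %in% FEATURE_KINDS)) {
    msgs <- c(msgs, paste("unknown feature kind(s):",
                          paste(unique(setdiff(m$type, FEATURE_KINDS)), collapse = ", ")))
  }
  str <- as.character(strand(gr))
  if (!all(str %in% c("+", "-"))) {
    msgs <- c(msgs, "all records must have strand '+' or '-'")
  }
  ec <- m$type %in% c("exon", "CDS")
  if (any(ec & (is.na(m$transcript_id) | m$transcript_id == ""))) {
    msgs <- c(msgs, "exon/CDS records must carry a non-empty transcript_id")
  }
  if (any(ec & (is.na(m$gene_id) | m$gene_id == ""))) {
    msgs <- c(msgs, "exon/CDS records must carry a non-empty gene_id")
  }
  has_tx <- !is.na(m$transcript_id) & m$transcript_id != ""
  if (any(has_tx)) {
    per_tx_chr <- tapply(as.character(seqnames(gr))[has_tx], m$transcript_id[has_tx],
                         function(x) length(unique(x)))
    per_tx_str <- tapply(str[has_tx], m$transcript_id[has_tx],
                         function(x) length(unique(x)))
    if (any(per_tx_chr > 1)) {
      msgs <- c(msgs, paste("transcript(s) span multiple seqnames:",
                            paste(names(per_tx_chr)[per_tx_chr > 1], collapse = ", ")))
    }
    if (any(per_tx_str > 1)) {
      msgs <- c(msgs, paste("transcript(s) carry conflicting strands:",
                            paste(names(per_tx_str)[per_tx_str > 1], collapse = ", ")))
    }
  }
  key <- paste(m$transcript_id, m$type, start(gr), end(gr), sep = "\r")
  if (anyDuplicated(key)) {
    msgs <- c(msgs, "duplicate (transcript_id, type, start, end) records")
  }
  cds_tx <- unique(m$transcript_id[m$type == "CDS"])
  exon_tx <- unique(m$transcript_id[m$type == "exon"])
  orphan_cds <- setdiff(cds_tx, exon_tx)
  if (length(orphan_cds) > 0) {
    msgs <- c(msgs, paste("transcript(s) have CDS but no exon records:",
                          paste(orphan_cds, collapse = ", ")))
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' GapMap: shared genomic-to-display coordinate transform
#'
#' A piecewise-linear, strictly increasing map from genomic to display
#' coordinates for one plotted locus.  Segments tile the locus without gaps;
#' segments covered by the union of displayed exons keep their genomic
#' length, uncovered segments (intronic/intergenic gaps) are compressed to at
#' most `cap` display units.  All transcripts of a gene are drawn through the
#' same map so they stay mutually aligned on one axis.
#'
#' @slot segments `data.frame` with columns `genomic_start`, `genomic_end`,
#'   `display_start`, `display_end`, `covered`; 1-based inclusive, sorted,
#'   contiguous in both coordinate systems.
#' @slot cap Maximum display length of any uncovered gap, in bp-equivalent
#'   display units.
#' @seealso [buildGapMap()], [applyGapMap()], [mapToDisplay()]
#' @export
setClass("GapMap",
  representation(segments = "data.frame", cap = "numeric")
)

setValidity("GapMap", function(object) {
  s <- object@segments
  need <- c("genomic_start", "genomic_end", "display_start", "display_end", "covered")
  if (!all(need %in% names(s))) {
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@cap) != 1 || is.na(object@cap) || object@cap <= 0) {
    return("cap must be a single positive number")
  }
  if (nrow(s) == 0) return("GapMap must contain at least one segment")
  msgs <- character()
  if (is.unsorted(s$genomic_start, strictly = TRUE)) {
    msgs <- c(msgs, "segments must be sorted by genomic_start")
  }
  if (any(s$genomic_end < s$genomic_start)) {
    msgs <- c(msgs, "segment genomic_end < genomic_start")
  }
  if (nrow(s) > 1) {
    if (any(s$genomic_start[-1] != s$genomic_end[-nrow(s)] + 1)) {
      msgs <- c(msgs, "segments must be contiguous in genomic space")
    }
    if (any(abs(s$display_start[-1] - (s$display_end[-nrow(s)] + 1)) > 1e-9)) {
      msgs <- c(msgs, "segments must be contiguous in display space")
    }
  }
  glen <- s$genomic_end - s$genomic_start + 1
  dlen <- s$display_end - s$display_start + 1
  if (any(dlen <= 0)) msgs <- c(msgs, "display lengths must be positive")
  if (any(s$covered & abs(dlen - glen) > 1e-9)) {
    msgs <- c(msgs, "covered segments must preserve genomic length")
  }
  bad_gap <- !s$covered & abs(dlen - pmin(glen, object@cap)) > 1e-9
  if (any(bad_gap)) {
    msgs <- c(msgs, "uncovered segments must have display length min(genomic length, cap)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' TranscriptExpression: transcript-by-sample expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]: rows are
#' transcripts, columns are samples.  The `counts` assay holds raw counts;
#' [normalizeCPM()] and [normalizeRelativeAbundance()] add `cpm` and
#' `relative_abundance` assays.  `rowData` may carry a `gene_id` column
#' (transcript-to-gene mapping) and `colData` carries sample metadata joined
#' by [joinMetadata()].
#'
#' @seealso [readExpression()], [longForm()], [normalizeCPM()],
#'   [normalizeRelativeAbundance()]
#' @export
#' @import SummarizedExperiment
setClass("TranscriptExpression", contains = "SummarizedExperiment")

setValidity("TranscriptExpression", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object)) {
    return("a 'counts' assay is required")
  }
  cnt <- assay(object, "counts")
  if (any(is.na(cnt)) || any(cnt < 0)) {
    msgs <- c(msgs, "raw counts must be non-negative and non-missing")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "transcript IDs (rownames) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msgs <- c(msgs, "sample IDs (colnames) must be present and unique")
  }
  if ("relative_abundance" %in% assayNames(object)) {
    ra <- assay(object, "relative_abundance")
    if (any(ra < -1e-9 | ra > 100 + 1e-9)) {
      msgs <- c(msgs, "relative_abundance must lie in [0, 100]")
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' FigureSpec: renderer-independent figure description
#'
#' A complete, renderer-independent description of the linked figure: one row
#' per displayed transcript (shared across panels), a transcript-structure
#' panel of shapes (exon boxes, taller CDS boxes, intron lines, strand
#' arrows) in display coordinates with per-shape hover payloads, and zero or
#' more expression panels of grouped boxplots with jittered raw points.
#' Render it with [exportHTML()] (interactive) or [exportStatic()].
#'
#' @slot rowOrder Character vector of transcript IDs, top row first.
#' @slot structure List produced by [makeStructurePanel()].
#' @slot panels List of expression-panel fragments (see
#'   [makeExpressionPanel()]).
#' @slot legendGroups Character vector of metadata group labels, one legend
#'   entry each.
#' @slot title Figure title.
#' @slot config List of display options (heights ratio, palette, jitter
#'   seed, dimensions).
#' @export
setClass("FigureSpec",
  representation(
    rowOrder = "character",
    structure = "list",
    panels = "list",
    legendGroups = "character",
    title = "character",
    config = "list"
  )
)

setValidity("FigureSpec", function(object) {
  msgs <- character()
  if (length(object@rowOrder) == 0) msgs <- c(msgs, "rowOrder must be non-empty")
  if (anyDuplicated(object@rowOrder)) msgs <- c(msgs, "rowOrder must be unique")
  for (p in object@panels) {
    if (!identical(p$rowOrder, object@rowOrder)) {
      msgs <- c(msgs, "all panels must share the figure rowOrder")
    }
  }
  if (length(object@structure) > 0 &&
      !identical(object@structure$rowOrder, object@rowOrder)) {
    msgs <- c(msgs, "structure panel rowOrder differs from figure rowOrder")
  }
  if (length(msgs) == 0) TRUE else msgs
})
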