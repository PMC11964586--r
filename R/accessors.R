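#' @include AllClasses.R
NULL

#' Construct a FeatureTable from a record data.frame
#'
#' Low-level constructor used by [readGTF()] and the fixture generator.
#' Expects 1-based inclusive coordinates.
#'
#' @param df data.frame with columns `seqname`, `source`, `type`, `start`,
#'   `end`, `strand`, `gene_id`, `gene_name`, `transcript_id`,
#'   `transcript_name`, `transcript_biotype`, `exon_number`.  Missing
#'   optional columns are filled with `NA`.
#' @param provenance list recording origin (path, options).
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(df, provenance = list()) {
  defaults <- list(
    source = NA_character_, gene_name = NA_character_,
    transcript_id = NA_character_, transcript_name = NA_character_,
    transcript_biotype = NA_character_, exon_number = NA_integer_
  )
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  gr <- GRanges(
    seqnames = as.character(df$seqname),
    ranges = IRanges(start = df$start, end = df$end),
    strand = as.character(df$strand)
  )
  mcols(gr) <- DataFrame(
    type = as.character(df$type),
    source = as.character(df$source),
    gene_id = as.character(df$gene_id),
    gene_name = as.character(df$gene_name),
    transcript_id = as.character(df$transcript_id),
    transcript_name = as.character(df$transcript_name),
    transcript_biotype = as.character(df$transcript_biotype),
    exon_number = as.integer(df$exon_number)
  )
  new("FeatureTable", records = gr, provenance = provenance)
}

#' @describeIn FeatureTable Number of records.
#' @param x A `FeatureTable`.
#' @export
setMethod("length", "FeatureTable", function(x) length(x@records))

#' Extract the records of a FeatureTable as a GRanges
#'
#' @param x A [FeatureTable-class].
#' @return A `GRanges` with the feature metadata columns.
#' @export
featureRecords <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@records
}

#' Extract the records of a FeatureTable as a plain data.frame
#'
#' Columns: `seqname`, `source`, `type`, `start`, `end`, `strand`,
#' `gene_id`, `gene_name`, `transcript_id`, `transcript_name`,
#' `transcript_biotype`, `exon_number`.  After [applyGapMap()] the `start`
#' and `end` columns hold display coordinates and the original genomic
#' coordinates appear as `genomic_start`/`genomic_end`.
#'
#' @param x A [FeatureTable-class].
#' @return data.frame, one row per record, in record order.
#' @export
featureFrame <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  gr <- x@records
  m <- as.data.frame(mcols(gr))
  out <- data.frame(
    seqname = as.character(seqnames(gr)),
    source = m$source,
    type = m$type,
    start = start(gr),
    end = end(gr),
    strand = as.character(strand(gr)),
    gene_id = m$gene_id,
    gene_name = m$gene_name,
    transcript_id = m$transcript_id,
    transcript_name = m$transcript_name,
    transcript_biotype = m$transcript_biotype,
    exon_number = m$exon_number,
    stringsAsFactors = FALSE
  )
  if ("genomic_start" %in% names(m)) {
    out$genomic_start <- m$genomic_start
    out$genomic_end <- m$genomic_end
  }
  rownames(out) <- NULL
  out
}

#' @describeIn FeatureTable Subset records by index or logical vector,
#'   preserving order and provenance.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  new("FeatureTable", records = x@records[i], provenance = x@provenance)
})

#' Provenance of a FeatureTable
#'
#' @param x A [FeatureTable-class].
#' @return The provenance list (source path, parse options).
#' @export
provenance <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@provenance
}

setMethod("show", "FeatureTable", function(object) {
  m <- mcols(object@records)
  ntx <- length(unique(m$transcript_id[!is.na(m$transcript_id) & m$transcript_id != ""]))
  ngene <- length(unique(m$gene_id[!is.na(m$gene_id)]))
  cat(sprintf("FeatureTable with %d records (%d genes, %d transcripts)\n",
              length(object@records), ngene, ntx))
  if (length(object@records) > 0) {
    tab <- table(m$type)
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(object@provenance$path)) {
    cat("  source:", object@provenance$path, "\n")
  }
  invisible(NULL)
})

#' Segments of a GapMap
#'
#' @param x A [GapMap-class].
#' @return The segment data.frame (`genomic_start`, `genomic_end`,
#'   `display_start`, `display_end`, `covered`).
#' @export
gapSegments <- function(x) {
  stopifnot(is(x, "GapMap"))
  x@segments
}

#' Gap cap of a GapMap
#'
#' @param x A [GapMap-class].
#' @return Maximum display length of an uncovered gap (display units).
#' @export
gapCap <- function(x) {
  stopifnot(is(x, "GapMap"))
  x@cap
}

setMethod("show", "GapMap", function(object) {
  s <- object@segments
  cat(sprintf("GapMap: %d segments over genomic [%d, %d] -> display [%g, %g], cap = %g\n",
              nrow(s), min(s$genomic_start), max(s$genomic_end),
              min(s$display_start), max(s$display_end), object@cap))
  cat(sprintf("  covered: %d segments (%d bp); gaps: %d (%d bp genomic, %g compressed)\n",
              sum(s$covered), sum((s$genomic_end - s$genomic_start + 1)[s$covered]),
              sum(!s$covered), sum((s$genomic_end - s$genomic_start + 1)[!s$covered]),
              sum((s$display_end - s$display_start + 1)[!s$covered])))
  invisible(NULL)
})

#' Construct a TranscriptExpression from a counts matrix
#'
#' @param counts numeric matrix, transcripts in rows (rownames = transcript
#'   IDs), samples in columns (colnames = sample IDs); non-negative.
#' @param geneId optional character vector (length `nrow(counts)`) mapping
#'   each transcript to its gene; stored in `rowData`.
#' @param colData optional data.frame of sample metadata (rownames or
#'   `sample_id` column matching colnames of `counts`).
#' @return A [TranscriptExpression-class] object.
#' @export
TranscriptExpression <- function(counts, geneId = NULL, colData = NULL) {
  counts <- as.matrix(counts)
  rd <- if (is.null(geneId)) NULL else DataFrame(gene_id = geneId, row.names = rownames(counts))
  if (!is.null(colData)) {
    colData <- as.data.frame(colData)
    if ("sample_id" %in% names(colData)) rownames(colData) <- colData$sample_id
    colData <- colData[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rd,
    colData = if (is.null(colData)) DataFrame(row.names = colnames(counts)) else colData
  )
  new("TranscriptExpression", se)
}

#' Raw counts assay
#' @param x A [TranscriptExpression-class].
#' @return Numeric matrix of raw counts.
#' @export
rawCounts <- function(x) assay(x, "counts")

#' Long-form view of a TranscriptExpression
#'
#' Melts the container to one row per (transcript, sample) with columns
#' `transcript_id`, `sample_id`, `raw_count`, plus `cpm` and
#' `relative_abundance` when computed, `gene_id` when known, and all sample
#' metadata columns.
#'
#' @param x A [TranscriptExpression-class].
#' @return data.frame in long form.
#' @export
longForm <- function(x) {
  stopifnot(is(x, "TranscriptExpression"))
  cnt <- assay(x, "counts")
  out <- data.frame(
    transcript_id = rep(rownames(cnt), times = ncol(cnt)),
    sample_id = rep(colnames(cnt), each = nrow(cnt)),
    raw_count = as.vector(cnt),
    stringsAsFactors = FALSE
  )
  for (a in intersect(c("cpm", "relative_abundance"), assayNames(x))) {
    out[[a]] <- as.vector(assay(x, a))
  }
  rd <- rowData(x)
  if ("gene_id" %in% colnames(rd)) {
    out$gene_id <- rep(rd$gene_id, times = ncol(cnt))
  }
  cd <- as.data.frame(colData(x))
  for (v in colnames(cd)) {
    if (v != "sample_id") out[[v]] <- rep(cd[[v]], each = nrow(cnt))
  }
  out
}

setMethod("show", "TranscriptExpression", function(object) {
  cat(sprintf("TranscriptExpression: %d transcripts x %d samples\n",
              nrow(object), ncol(object)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  rd <- rowData(object)
  if ("gene_id" %in% colnames(rd)) {
    cat(sprintf("  gene mapping: %d genes\n", length(unique(rd$gene_id))))
  }
  cd <- colData(object)
  if (ncol(cd) > 0) {
    cat("  sample metadata:", paste(colnames(cd), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Row order (displayed transcripts) of a FigureSpec
#' @param x A [FigureSpec-class].
#' @return Character vector of transcript IDs, top row first.
#' @export
rowOrder <- function(x) {
  stopifnot(is(x, "FigureSpec"))
  x@rowOrder
}

#' Legend groups of a FigureSpec
#' @param x A [FigureSpec-class].
#' @return Character vector of metadata group labels.
#' @export
legendGroups <- function(x) {
  stopifnot(is(x, "FigureSpec"))
  x@legendGroups
}

#' Panels of a FigureSpec
#' @param x A [FigureSpec-class].
#' @return List with the structure panel first, then expression panels.
#' @export
figurePanels <- function(x) {
  stopifnot(is(x, "FigureSpec"))
  c(if (length(x@structure) > 0) list(structure = x@structure) else list(), x@panels)
}

setMethod("show", "FigureSpec", function(object) {
  cat(sprintf("FigureSpec: %d transcript rows, %d expression panel(s)\n",
              length(object@rowOrder), length(object@panels)))
  if (length(object@structure) > 0) {
    cat(sprintf("  structure panel: %d shapes\n", nrow(object@structure$shapes)))
  }
  for (p in object@panels) {
    cat(sprintf("  expression panel '%s': %d boxes, %d points\n",
                p$metric, nrow(p$boxes), nrow(p$points)))
  }
  if (length(object@legendGroups) > 0) {
    cat("  legend groups:", paste(object@legendGroups, collapse = ", "), "\n")
  }
  invisible(NULL)
})
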