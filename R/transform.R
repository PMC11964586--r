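#' @include accessors.R
NULL

#' Transcript-to-gene mapping from an annotation
#'
#' @param annotation A [FeatureTable-class].
#' @return Named character vector: names are transcript IDs, values gene
#'   IDs, taken from exon/CDS records.
#' @export
transcriptGeneMap <- function(annotation) {
  stopifnot(is(annotation, "FeatureTable"))
  m <- mcols(annotation@records)
  sel <- !is.na(m$transcript_id) & m$transcript_id != ""
  tx <- m$transcript_id[sel]
  first <- !duplicated(tx)
  stats::setNames(m$gene_id[sel][first], tx[first])
}

#' Restrict annotation and expression to one gene
#'
#' Matches `gene` against `gene_id` and `gene_name` (exact, case-sensitive
#' unless `ignoreCase`); returns the annotation records of that gene and the
#' expression rows of its transcripts.  When no gene matches, the error
#' lists near-matches (identifiers sharing a prefix with the query) to help
#' with typos.
#'
#' @param annotation A [FeatureTable-class].
#' @param expr A [TranscriptExpression-class], or `NULL` for annotation-only
#'   filtering.
#' @param gene Gene identifier or symbol.
#' @param ignoreCase Match case-insensitively (default `FALSE`).
#' @return List with elements `annotation` ([FeatureTable-class]) and
#'   `expression` ([TranscriptExpression-class] or `NULL`).
#' @export
filterGene <- function(annotation, expr = NULL, gene, ignoreCase = FALSE) {
  stopifnot(is(annotation, "FeatureTable"), length(gene) == 1)
  m <- mcols(annotation@records)
  ids <- m$gene_id
  nms <- m$gene_name
  if (ignoreCase) {
    hit <- tolower(ids) == tolower(gene) | tolower(nms) == tolower(gene)
  } else {
    hit <- ids == gene | nms == gene
  }
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    universe <- unique(c(ids, nms))
    universe <- universe[!is.na(universe)]
    pfx <- substr(gene, 1, max(3, nchar(gene) - 2))
    near <- universe[startsWith(tolower(universe), tolower(pfx))]
    stop("gene '", gene, "' not found in annotation",
         if (length(near) > 0) paste0("; did you mean: ",
                                      paste(utils::head(sort(near), 5), collapse = ", "), "?"),
         call. = FALSE)
  }
  ann <- annotation[hit]
  out_expr <- NULL
  if (!is.null(expr)) {
    stopifnot(is(expr, "TranscriptExpression"))
    mm <- mcols(ann@records)
    tx <- unique(mm$transcript_id[!is.na(mm$transcript_id) & mm$transcript_id != ""])
    keep <- rownames(expr) %in% tx
    out_expr <- expr[keep, ]
  }
  list(annotation = ann, expression = out_expr)
}

#' Rank transcripts by expression and select the top ones
#'
#' Transcripts are ordered by `reducer(metric)` across samples, descending;
#' exact ties are broken by transcript ID ascending (C-locale lexicographic).
#'
#' @param expr A [TranscriptExpression-class] with the chosen metric
#'   computed.
#' @param metric One of `"raw_count"`, `"cpm"`, `"relative_abundance"`.
#' @param reducer One of `"mean"`, `"median"`, `"sum"` (default `"mean"`).
#' @param topN Number of transcripts to return; if larger than available,
#'   all are returned with a warning.
#' @return Character vector of transcript IDs in rank order.
#' @export
rankAndSelect <- function(expr, metric = c("raw_count", "cpm", "relative_abundance"),
                          reducer = c("mean", "median", "sum"), topN) {
  stopifnot(is(expr, "TranscriptExpression"))
  metric <- match.arg(metric)
  reducer <- match.arg(reducer)
  if (length(topN) != 1 || is.na(topN) || topN < 1 || topN != floor(topN)) {
    stop("topN must be a positive integer", call. = FALSE)
  }
  assay_name <- c(raw_count = "counts", cpm = "cpm",
                  relative_abundance = "relative_abundance")[[metric]]
  if (!assay_name %in% assayNames(expr)) {
    stop("metric '", metric, "' has not been computed; run ",
         if (metric == "cpm") "normalizeCPM()" else "normalizeRelativeAbundance()",
         " first", call. = FALSE)
  }
  mat <- assay(expr, assay_name)
  fun <- switch(reducer, mean = mean, median = stats::median, sum = sum)
  score <- apply(mat, 1, fun)
  ids <- rownames(mat)
  ord <- order(-score, ids, method = "radix")
  ranked <- ids[ord]
  if (topN > length(ranked)) {
    warning(sprintf("topN = %d exceeds the %d transcripts available; returning all",
                    topN, length(ranked)), call. = FALSE)
    topN <- length(ranked)
  }
  ranked[seq_len(topN)]
}

#' Number exons in transcription order
#'
#' Exons of each transcript are numbered 1..n in transcription order:
#' ascending genomic start on the `+` strand, descending on `-`.  CDS
#' records inherit the number of the exon that contains them.
#'
#' @param annotation A [FeatureTable-class] with exon records.
#' @return The annotation with `exon_number` filled on exon and CDS records.
#' @export
addExonNumber <- function(annotation) {
  stopifnot(is(annotation, "FeatureTable"))
  gr <- annotation@records
  m <- mcols(gr)
  num <- m$exon_number
  is_exon <- m$type == "exon"
  is_cds <- m$type == "CDS"
  for (tx in unique(m$transcript_id[is_exon])) {
    ei <- which(is_exon & m$transcript_id == tx)
    st <- start(gr)[ei]
    plus <- as.character(strand(gr)[ei[1]]) == "+"
    ord <- order(st, decreasing = !plus)
    num[ei[ord]] <- seq_along(ei)
    ci <- which(is_cds & m$transcript_id == tx)
    if (length(ci) > 0) {
      for (k in ci) {
        inside <- start(gr)[k] >= start(gr)[ei] & end(gr)[k] <= end(gr)[ei]
        if (!any(inside)) {
          stop("CDS record (", start(gr)[k], ", ", end(gr)[k],
               ") of transcript '", tx,
               "' is not contained in any of its exons", call. = FALSE)
        }
        num[k] <- num[ei[which(inside)[1]]]
      }
    }
  }
  orphan_cds <- unique(m$transcript_id[is_cds & !m$transcript_id %in% m$transcript_id[is_exon]])
  if (length(orphan_cds) > 0) {
    stop("CDS without exon records for transcript(s): ",
         paste(orphan_cds, collapse = ", "), call. = FALSE)
  }
  mcols(gr)$exon_number <- as.integer(num)
  new("FeatureTable", records = gr, provenance = annotation@provenance)
}

#' Derive intron records from exon records
#'
#' For each transcript, with exons sorted by start, appends an intron record
#' `(previous exon end + 1, next exon start - 1)` for each consecutive exon
#' pair; adjacent or abutting pairs produce no intron.  Overlapping exons
#' within one transcript are a validation error.
#'
#' @param annotation A [FeatureTable-class] with exon records.
#' @return The annotation with intron records appended (grouped by
#'   transcript, sorted by start within each transcript).
#' @export
toIntron <- function(annotation) {
  stopifnot(is(annotation, "FeatureTable"))
  df <- featureFrame(annotation)
  exons <- df[df$type == "exon", , drop = FALSE]
  introns <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    if (any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping exons within transcript '", tx, "'", call. = FALSE)
    }
    istart <- e$end[-nrow(e)] + 1
    iend <- e$start[-1] - 1
    keep <- iend >= istart
    if (!any(keep)) next
    it <- e[rep(1, sum(keep)), , drop = FALSE]
    it$type <- "intron"
    it$start <- istart[keep]
    it$end <- iend[keep]
    it$exon_number <- NA_integer_
    introns[[tx]] <- it
  }
  if (length(introns) == 0) return(annotation)
  out <- rbind(df, do.call(rbind, introns))
  FeatureTable(out, provenance = annotation@provenance)
}

#' Build a shared long-intron rescaling map for one locus
#'
#' Computes the union of exon intervals across all displayed transcripts;
#' regions covered by the union keep their genomic length in display space,
#' while each uncovered gap inside the locus span is compressed to at most
#' `cap` display units (gaps already at or below `cap` are untouched;
#' interior positions of a compressed gap map linearly).  The resulting
#' piecewise-linear map is shared by every displayed transcript, so all
#' isoforms of a gene stay aligned on one axis.
#'
#' @param annotation A [FeatureTable-class] restricted to one seqname.
#' @param cap Maximum display length of an uncovered gap, in bp-equivalent
#'   display units; a whole number >= 1 (default 100).
#' @param transcripts Transcript IDs to display (default: all transcripts
#'   with exons in `annotation`).
#' @return A [GapMap-class].
#' @export
buildGapMap <- function(annotation, cap = 100, transcripts = NULL) {
  stopifnot(is(annotation, "FeatureTable"))
  if (length(cap) != 1 || is.na(cap) || cap <= 0) {
    stop("cap must be a single positive number of display units", call. = FALSE)
  }
  if (cap != floor(cap)) {
    stop("cap must be a whole number of display units", call. = FALSE)
  }
  gr <- annotation@records
  m <- mcols(gr)
  sel <- m$type == "exon"
  if (!is.null(transcripts)) sel <- sel & m$transcript_id %in% transcripts
  if (!any(sel)) stop("no exon records among the displayed transcripts", call. = FALSE)
  ex <- gr[sel]
  if (length(unique(as.character(seqnames(ex)))) > 1) {
    stop("displayed transcripts span multiple seqnames: ",
         paste(unique(as.character(seqnames(ex))), collapse = ", "), call. = FALSE)
  }
  cov <- IRanges::reduce(IRanges(start(ex), end(ex)))
  cs <- IRanges::start(cov)
  ce <- IRanges::end(cov)
  n <- length(cs)
  seg <- data.frame(
    genomic_start = integer(0), genomic_end = integer(0), covered = logical(0)
  )
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(genomic_start = cs[i], genomic_end = ce[i],
                                           covered = TRUE)
    if (i < n && cs[i + 1] > ce[i] + 1) {
      rows[[length(rows) + 1]] <- data.frame(genomic_start = ce[i] + 1,
                                             genomic_end = cs[i + 1] - 1,
                                             covered = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  glen <- seg$genomic_end - seg$genomic_start + 1
  dlen <- ifelse(seg$covered, glen, pmin(glen, cap))
  dstart <- seg$genomic_start[1] + c(0, cumsum(dlen[-length(dlen)]))
  seg$display_start <- dstart
  seg$display_end <- dstart + dlen - 1
  seg <- seg[, c("genomic_start", "genomic_end", "display_start", "display_end",
                 "covered")]
  new("GapMap", segments = seg, cap = as.numeric(cap))
}

#' Map genomic positions to display coordinates
#'
#' Evaluates the piecewise-linear map of a [GapMap-class] at arbitrary
#' genomic positions within its domain (covered bases shift rigidly;
#' compressed gaps interpolate linearly).  The position one past the locus
#' end is also accepted, so interval ends can be mapped as
#' `mapToDisplay(map, end + 1) - 1`.
#'
#' @param map A [GapMap-class].
#' @param position Numeric vector of genomic positions.
#' @return Numeric vector of display coordinates (strictly increasing in
#'   `position`).
#' @export
mapToDisplay <- function(map, position) {
  stopifnot(is(map, "GapMap"))
  s <- map@segments
  lo <- s$genomic_start[1]
  hi <- s$genomic_end[nrow(s)]
  if (any(position < lo | position > hi + 1)) {
    stop(sprintf("position(s) outside the map domain [%d, %d]", lo, hi),
         call. = FALSE)
  }
  idx <- findInterval(position, s$genomic_start)
  glen <- s$genomic_end[idx] - s$genomic_start[idx] + 1
  dlen <- s$display_end[idx] - s$display_start[idx] + 1
  s$display_start[idx] + (position - s$genomic_start[idx]) * (dlen / glen)
}

#' Apply a gap map to annotation records
#'
#' Replaces every record's coordinates by display coordinates under the
#' map.  Exon and CDS records keep their genomic length exactly; intron
#' display lengths shrink to at most their genomic lengths; record order is
#' preserved.  The original genomic coordinates are retained in the
#' metadata columns `genomic_start`/`genomic_end` (used for hover text).
#'
#' @param map A [GapMap-class] built from the same displayed annotation.
#' @param annotation A [FeatureTable-class]; every record must lie within
#'   the map's genomic domain.
#' @return The annotation in display coordinates.
#' @export
applyGapMap <- function(map, annotation) {
  stopifnot(is(map, "GapMap"), is(annotation, "FeatureTable"))
  gr <- annotation@records
  if (length(gr) == 0) return(annotation)
  s <- map@segments
  lo <- s$genomic_start[1]
  hi <- s$genomic_end[nrow(s)]
  out_dom <- start(gr) < lo | end(gr) > hi
  if (any(out_dom)) {
    bad <- which(out_dom)[1]
    stop(sprintf("record %d (%d-%d) lies outside the map domain [%d, %d]",
                 bad, start(gr)[bad], end(gr)[bad], lo, hi), call. = FALSE)
  }
  gstart <- start(gr)
  gend <- end(gr)
  new_start <- mapToDisplay(map, gstart)
  new_end <- mapToDisplay(map, gend + 1) - 1
  # feature boundaries coincide with segment boundaries, so these are whole
  # numbers up to floating rounding
  new_start <- as.integer(round(new_start))
  new_end <- as.integer(round(new_end))
  keep_genomic <- mcols(gr)$genomic_start
  gr2 <- GRanges(seqnames(gr), IRanges(new_start, new_end), strand = strand(gr))
  mcols(gr2) <- mcols(gr)
  if (is.null(keep_genomic)) {
    mcols(gr2)$genomic_start <- gstart
    mcols(gr2)$genomic_end <- gend
  }
  new("FeatureTable", records = gr2, provenance = annotation@provenance)
}
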