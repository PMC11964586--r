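#' @include accessors.R
NULL

# Dark2-style qualitative palette, indexed by group order in the metadata.
DEFAULT_PALETTE <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                     "#66a61e", "#e6ab02", "#a6761d", "#666666")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

exonHover <- function(transcript, chrom, gstart, gend, exon_number, kind) {
  sprintf("%s<br>Transcript: %s<br>Chromosome: %s<br>Start: %d<br>End: %d<br>Length: %d bp<br>Exon number: %d",
          kind, transcript, chrom, gstart, gend, gend - gstart + 1, exon_number)
}

#' Build the transcript-structure panel of a figure
#'
#' One row per transcript (top row first): introns as horizontal lines with
#' strand-direction arrow markers at regular display intervals, exons as
#' boxes of height `h`, and CDS as boxes of height `2h` overdrawn on their
#' exons (protein-coding regions read as taller boxes).  Every exon/CDS
#' shape carries a hover payload with the transcript, chromosome, genomic
#' start and end, genomic length, and exon number; intron payloads carry
#' transcript, chromosome, coordinates and length.  Hover lengths are
#' always genomic (`end - start + 1`), never display lengths.
#'
#' @param annotation A [FeatureTable-class] in display coordinates (see
#'   [applyGapMap()]); must contain exon records (with `exon_number` set,
#'   see [addExonNumber()]) for every transcript in `rowOrder`.  Intron
#'   records ([toIntron()]) are drawn when present.
#' @param rowOrder Character vector of transcript IDs, top row first.
#' @param arrowSpacing Display-coordinate interval between strand arrows on
#'   intron lines (default 400).
#' @param exonHeight Height of a non-coding exon box in row units (default
#'   0.25); CDS boxes are twice this.
#' @return A structure-panel fragment (list) for [assembleFigure()].
#' @export
makeStructurePanel <- function(annotation, rowOrder, arrowSpacing = 400,
                               exonHeight = 0.25) {
  stopifnot(is(annotation, "FeatureTable"), length(rowOrder) > 0)
  df <- featureFrame(annotation)
  if (is.null(df$genomic_start)) {
    df$genomic_start <- df$start
    df$genomic_end <- df$end
  }
  have <- unique(df$transcript_id[df$type == "exon"])
  absent <- setdiff(rowOrder, have)
  if (length(absent) > 0) {
    stop("transcript(s) in row order have no exon records: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- df[df$transcript_id %in% rowOrder & df$type %in% c("exon", "CDS", "intron"), ,
           drop = FALSE]
  if (any(df$type == "exon" & is.na(df$exon_number))) {
    stop("exon records lack exon_number; run addExonNumber() first", call. = FALSE)
  }
  n <- length(rowOrder)
  ypos <- stats::setNames(n:1, rowOrder)   # top row first
  chrom <- df$seqname[1]
  shapes <- list()
  arrows <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    y <- ypos[[r$transcript_id]]
    if (r$type %in% c("exon", "CDS")) {
      h <- if (r$type == "CDS") exonHeight else exonHeight / 2
      shapes[[length(shapes) + 1]] <- data.frame(
        kind = r$type, transcript = r$transcript_id,
        x0 = r$start, x1 = r$end, y0 = y - h, y1 = y + h,
        hover = exonHover(r$transcript_id, r$seqname, r$genomic_start,
                          r$genomic_end, r$exon_number,
                          if (r$type == "CDS") "CDS" else "Exon"),
        stringsAsFactors = FALSE
      )
    } else {  # intron line
      shapes[[length(shapes) + 1]] <- data.frame(
        kind = "intron", transcript = r$transcript_id,
        x0 = r$start, x1 = r$end, y0 = y, y1 = y,
        hover = sprintf("Intron<br>Transcript: %s<br>Chromosome: %s<br>Start: %d<br>End: %d<br>Length: %d bp",
                        r$transcript_id, r$seqname, r$genomic_start,
                        r$genomic_end, r$genomic_end - r$genomic_start + 1),
        stringsAsFactors = FALSE
      )
      if (r$end - r$start >= arrowSpacing / 2) {
        at <- seq(r$start + arrowSpacing / 2, r$end, by = arrowSpacing)
      } else if (r$end - r$start >= 20) {
        at <- (r$start + r$end) / 2   # compressed introns still get one marker
      } else {
        at <- numeric(0)
      }
      if (length(at) > 0) {
        arrows[[length(arrows) + 1]] <- data.frame(
          transcript = r$transcript_id, x = at, y = y,
          direction = if (r$strand == "+") "right" else "left",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  shapes <- if (length(shapes) > 0) do.call(rbind, shapes) else
    data.frame(kind = character(0))
  arrows <- if (length(arrows) > 0) do.call(rbind, arrows) else
    data.frame(transcript = character(0), x = numeric(0), y = numeric(0),
               direction = character(0))
  xr <- range(c(df$start, df$end))
  list(
    kind = "structure",
    title = "Transcript Structure",
    rowOrder = rowOrder,
    ypos = ypos,
    shapes = shapes,
    arrows = arrows,
    chrom = chrom,
    exonHeight = exonHeight,
    xRange = xr
  )
}

#' Tukey box statistics per transcript and group
#'
#' Five-number summaries for grouped boxplots: median, quartiles by linear
#' interpolation (the common type-7 rule), fences at `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR`, whiskers at the most extreme data values inside the
#' fences (falling back to the quartile when no point lies beyond it), and
#' points outside the fences listed as outliers.  All raw points are
#' retained for overlay.
#'
#' @param expr A [TranscriptExpression-class] with sample metadata joined.
#' @param metric One of `"raw_count"`, `"cpm"`, `"relative_abundance"`
#'   (must be computed).
#' @param transcripts Transcript IDs to summarize.
#' @param groupVar Name of the metadata column to group by.
#' @return A data.frame of class `BoxStats`: one row per
#'   (transcript, group) with columns `transcript_id`, `group`, `n`,
#'   `median`, `lower_quartile`, `upper_quartile`, `iqr`, `fence_low`,
#'   `fence_high`, `whisker_low`, `whisker_high`, and list columns
#'   `outliers`, `points`, `samples`.
#' @export
computeBoxStats <- function(expr, metric = c("raw_count", "cpm", "relative_abundance"),
                            transcripts, groupVar) {
  stopifnot(is(expr, "TranscriptExpression"))
  metric <- match.arg(metric)
  cd <- as.data.frame(colData(expr))
  if (!groupVar %in% names(cd)) {
    stop("grouping variable '", groupVar, "' not found in sample metadata",
         " (have: ", paste(names(cd), collapse = ", "), ")", call. = FALSE)
  }
  assay_name <- c(raw_count = "counts", cpm = "cpm",
                  relative_abundance = "relative_abundance")[[metric]]
  if (!assay_name %in% assayNames(expr)) {
    stop("metric '", metric, "' has not been computed", call. = FALSE)
  }
  absent <- setdiff(transcripts, rownames(expr))
  if (length(absent) > 0) {
    stop("transcript(s) absent from expression data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  mat <- assay(expr, assay_name)
  groups <- unique(as.character(cd[[groupVar]]))
  rows <- list()
  for (tx in transcripts) {
    for (g in groups) {
      sel <- as.character(cd[[groupVar]]) == g
      x <- as.numeric(mat[tx, sel])
      smp <- colnames(mat)[sel]
      if (length(x) == 0) {
        warning("no samples in group '", g, "'; empty box for ", tx, call. = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          transcript_id = tx, group = g, n = 0L,
          median = NA_real_, lower_quartile = NA_real_, upper_quartile = NA_real_,
          iqr = NA_real_, fence_low = NA_real_, fence_high = NA_real_,
          whisker_low = NA_real_, whisker_high = NA_real_,
          stringsAsFactors = FALSE
        )
        rows[[length(rows)]]$outliers <- list(numeric(0))
        rows[[length(rows)]]$points <- list(numeric(0))
        rows[[length(rows)]]$samples <- list(character(0))
        next
      }
      q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3] - q[1]
      fl <- q[1] - 1.5 * iqr
      fh <- q[3] + 1.5 * iqr
      inside_lo <- x[x >= fl]
      inside_hi <- x[x <= fh]
      wl <- if (length(inside_lo) > 0) min(inside_lo) else q[1]
      wh <- if (length(inside_hi) > 0) max(inside_hi) else q[3]
      out <- x[x < fl | x > fh]
      row <- data.frame(
        transcript_id = tx, group = g, n = length(x),
        median = q[2], lower_quartile = q[1], upper_quartile = q[3],
        iqr = iqr, fence_low = fl, fence_high = fh,
        whisker_low = wl, whisker_high = wh,
        stringsAsFactors = FALSE
      )
      row$outliers <- list(out)
      row$points <- list(x)
      row$samples <- list(smp)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("BoxStats", class(out))
  out
}

#' Build one expression panel (grouped boxplots with jittered points)
#'
#' Horizontal grouped boxplots of the chosen metric, one row per transcript
#' in the shared row order, dodged by metadata group, overlaid with
#' deterministically jittered raw data points (fixed seed, so identical
#' inputs produce identical figures).
#'
#' @param expr A [TranscriptExpression-class] with metadata joined and the
#'   metric computed.
#' @param metric One of `"raw_count"`, `"cpm"`, `"relative_abundance"`.
#' @param rowOrder Character vector of transcript IDs, top row first
#'   (shared with the structure panel).
#' @param groupVar Metadata column to group and color by.
#' @param jitterSeed Seed for the point jitter (default 1).
#' @return An expression-panel fragment (list) for [assembleFigure()].
#' @export
makeExpressionPanel <- function(expr, metric = c("raw_count", "cpm", "relative_abundance"),
                                rowOrder, groupVar, jitterSeed = 1) {
  metric <- match.arg(metric)
  stats <- computeBoxStats(expr, metric, rowOrder, groupVar)
  groups <- unique(stats$group)
  n <- length(rowOrder)
  ng <- length(groups)
  ypos <- stats::setNames(n:1, rowOrder)
  slot_h <- 0.8                      # vertical space per row devoted to boxes
  box_h <- slot_h / ng
  offset <- stats::setNames((match(groups, groups) - (ng + 1) / 2) * box_h, groups)
  stats$y <- ypos[stats$transcript_id] + offset[stats$group]
  stats$box_half <- 0.38 * box_h
  pts <- list()
  for (i in seq_len(nrow(stats))) {
    v <- stats$points[[i]]
    if (length(v) == 0) next
    pts[[length(pts) + 1]] <- data.frame(
      transcript = stats$transcript_id[i], group = stats$group[i],
      sample = stats$samples[[i]], value = v,
      y_center = stats$y[i], stringsAsFactors = FALSE
    )
  }
  pts <- if (length(pts) > 0) do.call(rbind, pts) else
    data.frame(transcript = character(0), group = character(0),
               sample = character(0), value = numeric(0), y_center = numeric(0))
  jit <- withSeed(jitterSeed,
                  stats::runif(nrow(pts), -0.3 * box_h, 0.3 * box_h))
  pts$y <- pts$y_center + jit
  pts$hover <- sprintf("Sample: %s<br>Group: %s<br>Transcript: %s<br>%s: %s",
                       pts$sample, pts$group, pts$transcript,
                       metricLabel(metric), formatC(pts$value, format = "fg", digits = 6))
  rownames(pts) <- NULL
  vals <- c(unlist(stats$points), 0)
  list(
    kind = "expression",
    metric = metric,
    title = metricLabel(metric),
    rowOrder = rowOrder,
    ypos = ypos,
    groups = groups,
    groupVar = groupVar,
    boxes = stats,
    points = pts,
    jitterSeed = jitterSeed,
    xRange = range(vals)
  )
}

metricLabel <- function(metric) {
  c(raw_count = "Counts", cpm = "CPM",
    relative_abundance = "Relative abundance (%)")[[metric]]
}

#' Assemble the linked figure
#'
#' Combines the structure panel and any number of expression panels into a
#' single [FigureSpec-class] with one shared vertical axis: every
#' transcript occupies the same row in every panel.  Each metadata group
#' gets exactly one legend entry that toggles that group's boxes and points
#' across all expression panels simultaneously.
#'
#' @param structure Structure-panel fragment from [makeStructurePanel()],
#'   or `NULL` for an expression-only figure.
#' @param expressionPanels List of fragments from [makeExpressionPanel()]
#'   (may be empty for a structure-only figure).
#' @param rowOrder Shared transcript row order, top row first.
#' @param title Figure title (default "").
#' @param palette Colors indexed by group order (default: built-in
#'   qualitative palette).
#' @return A [FigureSpec-class].
#' @export
assembleFigure <- function(structure = NULL, expressionPanels = list(),
                           rowOrder, title = "", palette = DEFAULT_PALETTE) {
  if (is.null(structure) && length(expressionPanels) == 0) {
    stop("nothing to assemble: need a structure panel or expression panels",
         call. = FALSE)
  }
  if (!is.null(structure) && !identical(structure$rowOrder, rowOrder)) {
    stop("assembly error: structure panel row order differs from the shared row order",
         call. = FALSE)
  }
  groups <- character(0)
  for (p in expressionPanels) {
    if (!identical(p$rowOrder, rowOrder)) {
      stop("assembly error: expression panel '", p$metric,
           "' row order differs from the shared row order", call. = FALSE)
    }
    groups <- union(groups, p$groups)
  }
  jseed <- if (length(expressionPanels) > 0) expressionPanels[[1]]$jitterSeed else 1
  new("FigureSpec",
      rowOrder = rowOrder,
      structure = if (is.null(structure)) list() else structure,
      panels = expressionPanels,
      legendGroups = groups,
      title = title,
      config = list(
        palette = stats::setNames(rep(palette, length.out = max(length(groups), 1))[seq_along(groups)],
                                  groups),
        jitterSeed = jseed,
        heightsRatio = 2
      ))
}
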