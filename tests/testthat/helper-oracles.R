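# Shared helpers: tiny annotation builders and independent brute-force
# oracles used against the package implementations.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Quick FeatureTable from minimal exon/CDS descriptions.
toyAnnotation <- function(..., seqname = "chr1", strand = "+") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      seqname = seqname, source = "toy", type = r$type,
      start = r$start, end = r$end,
      strand = if (!is.null(r$strand)) r$strand else strand,
      gene_id = if (!is.null(r$gene)) r$gene else "G1",
      gene_name = if (!is.null(r$gene)) r$gene else "G1",
      transcript_id = r$tx, transcript_name = r$tx,
      transcript_biotype = NA_character_,
      exon_number = NA_integer_, stringsAsFactors = FALSE
    )
  }))
  FeatureTable(df)
}

exonRow <- function(tx, start, end, type = "exon", strand = NULL, gene = NULL) {
  list(tx = tx, start = start, end = end, type = type, strand = strand,
       gene = gene)
}

# Brute-force per-base genomic->display map oracle.  Walks the locus base by
# base: a covered base advances display by 1; inside an uncovered gap every
# base advances by min(gap, cap)/gap so the gap's display total is exactly
# min(gap, cap).  Returns a query function for positions in [lo, hi + 1].
brutePerBaseMap <- function(exonStarts, exonEnds, cap) {
  lo <- min(exonStarts)
  hi <- max(exonEnds)
  nb <- hi - lo + 1
  covered <- logical(nb)
  for (i in seq_along(exonStarts)) {
    covered[(exonStarts[i] - lo + 1):(exonEnds[i] - lo + 1)] <- TRUE
  }
  d <- numeric(nb + 1)  # d[k] = display coordinate of genomic position lo + k - 1
  d[1] <- lo
  runs <- rle(covered)
  idx <- 1
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (runs$values[r]) {
      d[idx + seq_len(len)] <- d[idx] + seq_len(len)
    } else {
      dlen <- min(len, cap)
      d[idx + seq_len(len)] <- d[idx] + seq_len(len) * (dlen / len)
      d[idx + len] <- d[idx] + dlen  # gap total exact by construction
    }
    idx <- idx + len
  }
  function(pos) {
    stopifnot(all(pos >= lo & pos <= hi + 1))
    d[pos - lo + 1]
  }
}

# Independent type-7 quartile / Tukey fence computation from first
# principles (sorted order statistics + linear interpolation).
bruteBoxStats <- function(x) {
  s <- sort(x)
  n <- length(s)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    (1 - (h - lo)) * s[lo] + (h - lo) * s[hi]
  }
  q1 <- q7(0.25); med <- q7(0.5); q3 <- q7(0.75)
  iqr <- q3 - q1
  fl <- q1 - 1.5 * iqr
  fh <- q3 + 1.5 * iqr
  list(
    median = med, lower_quartile = q1, upper_quartile = q3, iqr = iqr,
    fence_low = fl, fence_high = fh,
    whisker_low = if (any(s >= fl)) min(s[s >= fl]) else q1,
    whisker_high = if (any(s <= fh)) max(s[s <= fh]) else q3,
    outliers = s[s < fl | s > fh]
  )
}

# Random single-locus annotation: a few transcripts with non-overlapping
# exons each, drawn over a <= 50 kb locus.  Used by the gap-map oracle
# sweeps.
randomLocus <- function(max_span = 50000, max_tx = 4) {
  n_tx <- sample.int(max_tx, 1)
  rows <- list()
  for (t in seq_len(n_tx)) {
    n_ex <- sample(1:8, 1)
    bounds <- sort(sample.int(max_span, 2 * n_ex))
    starts <- bounds[seq(1, 2 * n_ex, by = 2)]
    ends <- bounds[seq(2, 2 * n_ex, by = 2)]
    # enforce a 1-bp separation so exons of one transcript never touch
    ok <- c(TRUE, starts[-1] > ends[-n_ex] + 1)
    starts <- starts[ok]; ends <- ends[ok]
    for (i in seq_along(starts)) {
      rows[[length(rows) + 1]] <- exonRow(sprintf("T%02d", t), starts[i], ends[i])
    }
  }
  do.call(toyAnnotation, rows)
}

expectedSixFields <- c("Transcript:", "Chromosome:", "Start:", "End:",
                       "Length:", "Exon number:")
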