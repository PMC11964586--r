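#' @include accessors.R
NULL

#' Configuration for the synthetic fixture generator
#'
#' Describes a small but structurally complete dataset: multi-transcript
#' genes on both strands, CDS subsets of exons, at least one gene with six
#' or more isoforms (so top-N selection is exercised) and at least one
#' intron much longer than the default rescale cap, plus negative-binomial
#' counts with a per-gene group fold-change over two sample groups.  The
#' defaults mirror a small case/control isoform study: eight samples in two
#' groups of four, one focal gene with many isoforms.
#'
#' @param nGenes Number of genes (default 3).
#' @param transcriptsPerGene Integer range, transcripts per gene (default
#'   `c(2, 8)`); whenever the range allows it, the first gene is given at
#'   least 6 so top-N selection is exercised.
#' @param unionExonsPerGene Integer range, distinct exons in a gene's exon
#'   chain (default `c(4, 10)`).
#' @param exonsPerTranscript Integer range, exons used by one transcript
#'   (default `c(1, 9)`, capped at the gene's chain length); the first
#'   transcript of each gene uses the full chain.
#' @param exonLengthRange Exon lengths in bp (default `c(50, 300)`).
#' @param intronLengthRange Ordinary gap lengths in bp (default
#'   `c(60, 900)`).
#' @param longIntronLength Length of the one guaranteed long gap per gene,
#'   in bp (default 5000; at least 10 times the default rescale cap of
#'   100).
#' @param cdsFraction Share of transcripts that are protein-coding
#'   (default 0.7).
#' @param nSamplesPerGroup Samples per group (default 4).
#' @param groupLabels Two group labels (default `c("case", "control")`).
#' @param nbMeanRange Range of per-transcript negative-binomial means,
#'   sampled log-uniformly (default `c(20, 2000)`).
#' @param nbDispersion Negative-binomial dispersion; the NB size parameter
#'   is `1/nbDispersion` (default 0.3).
#' @param log2FoldChangeRange Per-gene group log2 fold-change sampled
#'   uniformly from this range and applied to the second group (default
#'   `c(-1.5, 1.5)`).
#' @param dropTranscripts Number of transcripts omitted from the counts
#'   matrix (default 0; used to exercise consistency reports).
#' @param seed Random seed; the same seed gives byte-identical outputs.
#' @return A validated `FixtureConfig` list.
#' @export
fixtureConfig <- function(nGenes = 3,
                          transcriptsPerGene = c(2, 8),
                          unionExonsPerGene = c(4, 10),
                          exonsPerTranscript = c(1, 9),
                          exonLengthRange = c(50, 300),
                          intronLengthRange = c(60, 900),
                          longIntronLength = 5000,
                          cdsFraction = 0.7,
                          nSamplesPerGroup = 4,
                          groupLabels = c("case", "control"),
                          nbMeanRange = c(20, 2000),
                          nbDispersion = 0.3,
                          log2FoldChangeRange = c(-1.5, 1.5),
                          dropTranscripts = 0,
                          seed = 1) {
  cfg <- list(
    nGenes = nGenes, transcriptsPerGene = transcriptsPerGene,
    unionExonsPerGene = unionExonsPerGene,
    exonsPerTranscript = exonsPerTranscript,
    exonLengthRange = exonLengthRange,
    intronLengthRange = intronLengthRange,
    longIntronLength = longIntronLength,
    cdsFraction = cdsFraction, nSamplesPerGroup = nSamplesPerGroup,
    groupLabels = groupLabels, nbMeanRange = nbMeanRange,
    nbDispersion = nbDispersion,
    log2FoldChangeRange = log2FoldChangeRange,
    dropTranscripts = dropTranscripts, seed = seed
  )
  for (nm in c("transcriptsPerGene", "unionExonsPerGene", "exonsPerTranscript",
               "exonLengthRange", "intronLengthRange", "nbMeanRange",
               "log2FoldChangeRange")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2]) {
      stop("invalid range for ", nm, ": min must not exceed max", call. = FALSE)
    }
  }
  if (nGenes < 1) stop("nGenes must be at least 1", call. = FALSE)
  if (length(groupLabels) != 2) stop("exactly two group labels are required", call. = FALSE)
  if (longIntronLength < 1000) {
    stop("longIntronLength must be at least 1000 (10x the default rescale cap)",
         call. = FALSE)
  }
  class(cfg) <- c("FixtureConfig", "list")
  cfg
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Lay out one gene: a chain of union exons separated by gaps, one of which
# is the guaranteed long gap.  Returns the chain and per-transcript
# exon/CDS/intron layout.
layoutGene <- function(cfg, g) {
  gene_id <- sprintf("GENE%03d", g)
  n_union <- rint(1, cfg$unionExonsPerGene)
  if (n_union < 2) n_union <- 2   # need at least one gap for the long intron
  exon_len <- rint(n_union, cfg$exonLengthRange)
  gap_len <- if (n_union > 1) rint(n_union - 1, cfg$intronLengthRange) else integer(0)
  long_at <- sample(seq_len(n_union - 1), 1)
  gap_len[long_at] <- cfg$longIntronLength
  starts <- integer(n_union)
  pos <- 1000L + g  # arbitrary locus origin, different per gene
  for (i in seq_len(n_union)) {
    starts[i] <- pos
    pos <- pos + exon_len[i] + if (i < n_union) gap_len[i] else 0L
  }
  union_exons <- data.frame(start = starts, end = starts + exon_len - 1L)
  n_tx <- rint(1, cfg$transcriptsPerGene)
  if (g == 1 && cfg$transcriptsPerGene[2] >= 6) {
    n_tx <- max(n_tx, 6L)  # guarantee a gene that exercises top-N selection
  }
  strand <- if (g %% 2 == 1) "+" else "-"
  n_coding <- ceiling(cfg$cdsFraction * n_tx)
  txs <- vector("list", n_tx)
  for (t in seq_len(n_tx)) {
    if (t == 1) {
      use <- seq_len(n_union)   # canonical isoform covers the full chain
    } else {
      k <- min(rint(1, cfg$exonsPerTranscript), n_union)
      k <- max(k, 1)
      use <- sort(sample(seq_len(n_union), k))
    }
    ex <- union_exons[use, , drop = FALSE]
    introns <- if (nrow(ex) > 1) {
      data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    cds <- NULL
    if (t <= n_coding) {
      a <- sample(seq_len(nrow(ex)), 1)
      b <- sample(seq(a, nrow(ex)), 1)
      cds_start <- ex$start[a] + sample.int(max(ex$end[a] - ex$start[a], 1), 1) - 1L
      cds_end <- ex$end[b] - sample.int(max(ex$end[b] - ex$start[b], 1), 1) + 1L
      if (a == b && cds_start > cds_end) {
        mid <- (ex$start[a] + ex$end[a]) %/% 2
        cds_start <- mid; cds_end <- mid
      }
      if (cds_start > cds_end) { cds_start <- ex$start[a]; cds_end <- ex$end[b] }
      sel <- ex$end >= cds_start & ex$start <= cds_end
      cds <- data.frame(start = pmax(ex$start[sel], cds_start),
                        end = pmin(ex$end[sel], cds_end))
    }
    txs[[t]] <- list(
      transcript_id = sprintf("%s.T%02d", gene_id, t),
      exons = ex, introns = introns, cds = cds,
      biotype = if (t <= n_coding) "protein_coding" else "processed_transcript"
    )
  }
  list(
    gene_id = gene_id,
    gene_name = sprintf("Gene%d", g),
    seqname = sprintf("chr%d", g),
    strand = strand,
    union_exons = union_exons,
    gap_len = gap_len,
    transcripts = txs
  )
}

# Truth gap map for one gene under a given cap, derived from the known
# union-exon chain layout (not from the interval algebra under test).
truthGapMap <- function(gene, cap) {
  ue <- gene$union_exons
  segs <- list()
  for (i in seq_len(nrow(ue))) {
    segs[[length(segs) + 1]] <- c(ue$start[i], ue$end[i], TRUE)
    if (i < nrow(ue)) {
      segs[[length(segs) + 1]] <- c(ue$end[i] + 1, ue$start[i + 1] - 1, FALSE)
    }
  }
  m <- do.call(rbind, segs)
  glen <- m[, 2] - m[, 1] + 1
  dlen <- ifelse(m[, 3] == 1, glen, pmin(glen, cap))
  ds <- m[1, 1] + c(0, cumsum(dlen[-length(dlen)]))
  data.frame(genomic_start = m[, 1], genomic_end = m[, 2],
             display_start = ds, display_end = ds + dlen - 1,
             covered = m[, 3] == 1)
}

#' Generate a synthetic annotation + expression fixture
#'
#' Writes a parseable GTF (gene, transcript, exon and CDS rows), a wide
#' counts matrix (CSV), sample metadata (CSV) and a machine-readable truth
#' record (JSON) with the expected per-gene transcript ranking, per-
#' transcript intron coordinates, and per-gene gap-map segments for the
#' default rescale cap — the quantities test oracles compare against.
#' Identical configurations (same seed) produce byte-identical files.
#'
#' @param config A [fixtureConfig()] list.
#' @param outDir Output directory (created if needed).
#' @return List with `gtf`, `counts`, `metadata`, `truthPath` (file paths)
#'   and `truth` (the truth record as an R list).
#' @export
generateFixture <- function(config = fixtureConfig(), outDir = tempfile("fixture")) {
  stopifnot(inherits(config, "FixtureConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  withSeed(config$seed, {
    genes <- lapply(seq_len(config$nGenes), function(g) layoutGene(config, g))
    rows <- list()
    for (gn in genes) {
      g_start <- min(vapply(gn$transcripts, function(t) min(t$exons$start), numeric(1)))
      g_end <- max(vapply(gn$transcripts, function(t) max(t$exons$end), numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(
        seqname = gn$seqname, source = "fixture", type = "gene",
        start = g_start, end = g_end, strand = gn$strand,
        gene_id = gn$gene_id, gene_name = gn$gene_name,
        transcript_id = NA_character_, transcript_name = NA_character_,
        transcript_biotype = NA_character_, exon_number = NA_integer_,
        stringsAsFactors = FALSE
      )
      for (tx in gn$transcripts) {
        base <- data.frame(
          seqname = gn$seqname, source = "fixture", type = "transcript",
          start = min(tx$exons$start), end = max(tx$exons$end),
          strand = gn$strand, gene_id = gn$gene_id, gene_name = gn$gene_name,
          transcript_id = tx$transcript_id,
          transcript_name = paste0(gn$gene_name, "-", sub("^.*\\.", "", tx$transcript_id)),
          transcript_biotype = tx$biotype, exon_number = NA_integer_,
          stringsAsFactors = FALSE
        )
        rows[[length(rows) + 1]] <- base
        for (i in seq_len(nrow(tx$exons))) {
          r <- base; r$type <- "exon"
          r$start <- tx$exons$start[i]; r$end <- tx$exons$end[i]
          rows[[length(rows) + 1]] <- r
        }
        if (!is.null(tx$cds)) {
          for (i in seq_len(nrow(tx$cds))) {
            r <- base; r$type <- "CDS"
            r$start <- tx$cds$start[i]; r$end <- tx$cds$end[i]
            rows[[length(rows) + 1]] <- r
          }
        }
      }
    }
    ann_df <- do.call(rbind, rows)
    ann <- FeatureTable(ann_df, provenance = list(path = "generated"))
    gtf_path <- file.path(outDir, "fixture.gtf")
    writeGTF(ann, gtf_path)

    # counts: NB with per-transcript means and a gene-level group fold-change
    all_tx <- unlist(lapply(genes, function(gn)
      vapply(gn$transcripts, `[[`, character(1), "transcript_id")))
    ns <- config$nSamplesPerGroup
    samples <- c(paste0(config$groupLabels[1], "_", seq_len(ns)),
                 paste0(config$groupLabels[2], "_", seq_len(ns)))
    group <- rep(config$groupLabels, each = ns)
    lfc <- stats::runif(length(genes), config$log2FoldChangeRange[1],
                        config$log2FoldChangeRange[2])
    mu1 <- exp(stats::runif(length(all_tx), log(config$nbMeanRange[1]),
                            log(config$nbMeanRange[2])))
    gene_of_tx <- unlist(lapply(seq_along(genes), function(i)
      rep(i, length(genes[[i]]$transcripts))))
    mu2 <- mu1 * 2^lfc[gene_of_tx]
    size <- 1 / config$nbDispersion
    cnt <- matrix(0L, nrow = length(all_tx), ncol = 2 * ns,
                  dimnames = list(all_tx, samples))
    for (i in seq_along(all_tx)) {
      cnt[i, seq_len(ns)] <- stats::rnbinom(ns, mu = mu1[i], size = size)
      cnt[i, ns + seq_len(ns)] <- stats::rnbinom(ns, mu = mu2[i], size = size)
    }
    kept_tx <- all_tx
    if (config$dropTranscripts > 0) {
      drop <- sample(all_tx, min(config$dropTranscripts, length(all_tx)))
      kept_tx <- setdiff(all_tx, drop)
    }
    counts_path <- file.path(outDir, "counts.csv")
    counts_df <- data.frame(transcript_id = kept_tx,
                            cnt[kept_tx, , drop = FALSE],
                            check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(counts_df, counts_path, row.names = FALSE, quote = FALSE)

    meta_path <- file.path(outDir, "metadata.csv")
    utils::write.csv(data.frame(sample_id = samples, condition = group,
                                stringsAsFactors = FALSE),
                     meta_path, row.names = FALSE, quote = FALSE)

    # truth record: expected ranks from the realized counts, intron
    # coordinates and gap-map segments from the known layout
    truth <- list(seed = config$seed, cap = 100, samples = samples,
                  groups = group, genes = list())
    for (gi in seq_along(genes)) {
      gn <- genes[[gi]]
      tx_ids <- vapply(gn$transcripts, `[[`, character(1), "transcript_id")
      means <- rowMeans(cnt[tx_ids, , drop = FALSE])
      ord <- order(-means, tx_ids, method = "radix")
      gm <- truthGapMap(gn, 100)
      truth$genes[[gn$gene_id]] <- list(
        gene_id = gn$gene_id, gene_name = gn$gene_name,
        seqname = gn$seqname, strand = gn$strand,
        log2_fold_change = lfc[gi],
        expected_rank = tx_ids[ord],
        mean_counts = as.list(stats::setNames(unname(means), tx_ids)),
        gap_map = gm,
        transcripts = lapply(gn$transcripts, function(tx) list(
          transcript_id = tx$transcript_id,
          exons = unname(as.matrix(tx$exons)),
          introns = unname(as.matrix(tx$introns)),
          cds = if (is.null(tx$cds)) matrix(numeric(0), ncol = 2)
                else unname(as.matrix(tx$cds))
        ))
      )
    }
    truth_path <- file.path(outDir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    list(gtf = gtf_path, counts = counts_path, metadata = meta_path,
         truthPath = truth_path, truth = truth)
  })
}
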