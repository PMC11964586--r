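#' @include accessors.R
NULL

readRectangular <- function(path, sheet = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading XLSX requires the 'readxl' package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet),
                    check.names = FALSE, stringsAsFactors = FALSE)
    },
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("reading Parquet requires the 'arrow' package", call. = FALSE)
      }
      as.data.frame(arrow::read_parquet(path))
    },
    stop("unsupported expression file extension '", ext,
         "' (expected csv, tsv, txt, xlsx or parquet)", call. = FALSE)
  )
  df
}

#' Read a transcript-level expression matrix
#'
#' Reads a wide counts table (one transcript-ID column plus one numeric
#' column per sample) from TSV, CSV, XLSX or Parquet, dispatched by file
#' extension.  Missing cells are treated as 0 with a warning; non-numeric
#' text in a sample column is an error.
#'
#' @param path Input file.
#' @param idColumn Name of the transcript-ID column (default
#'   `"transcript_id"`).
#' @param sheet For XLSX input only: sheet name or index (default: first
#'   sheet).
#' @return A [TranscriptExpression-class] with a `counts` assay.
#' @export
readExpression <- function(path, idColumn = "transcript_id", sheet = NULL) {
  df <- readRectangular(path, sheet = sheet)
  if (!idColumn %in% names(df)) {
    stop("ID column '", idColumn, "' not found in '", path, "'; columns are: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  ids <- as.character(df[[idColumn]])
  if (anyDuplicated(ids)) {
    stop("duplicate transcript IDs in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(df), idColumn)
  if (length(sample_cols) == 0) stop("no sample columns in '", path, "'", call. = FALSE)
  n_missing <- 0L
  mat <- sapply(sample_cols, function(sc) {
    v <- df[[sc]]
    if (is.character(v)) {
      blank <- is.na(v) | trimws(v) == ""
      num <- suppressWarnings(as.numeric(v))
      bad <- !blank & is.na(num)
      if (any(bad)) {
        stop(sprintf("non-numeric value '%s' in sample column '%s' (transcript %s)",
                     v[which(bad)[1]], sc, ids[which(bad)[1]]), call. = FALSE)
      }
      v <- num
    }
    if (!is.numeric(v)) {
      stop("sample column '", sc, "' is not numeric", call. = FALSE)
    }
    n_missing <<- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, sample_cols))
  if (n_missing > 0) {
    warning(sprintf("%d missing cell(s) in '%s' treated as 0", n_missing, path),
            call. = FALSE)
  }
  TranscriptExpression(mat)
}

#' Read a sample metadata table
#'
#' @param path CSV or TSV file with one row per sample; one column holds the
#'   sample identifier, the rest are grouping variables (e.g. case/control).
#' @param sampleColumn Name of the sample-ID column (default `"sample_id"`).
#' @return data.frame with rownames set to the sample IDs.
#' @export
readSampleMetadata <- function(path, sampleColumn = "sample_id") {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    stop("unsupported metadata extension '", ext, "' (expected csv or tsv)",
         call. = FALSE)
  )
  if (!sampleColumn %in% names(df)) {
    stop("sample column '", sampleColumn, "' not found in '", path, "'",
         call. = FALSE)
  }
  ids <- as.character(df[[sampleColumn]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(df)[names(df) == sampleColumn] <- "sample_id"
  df$sample_id <- ids
  rownames(df) <- ids
  df
}

#' Join sample metadata onto a TranscriptExpression
#'
#' Attaches the grouping variables of `meta` to the container's `colData`.
#' Every expression sample must appear in the metadata; metadata rows for
#' samples absent from the expression matrix are ignored.
#'
#' @param expr A [TranscriptExpression-class].
#' @param meta data.frame as returned by [readSampleMetadata()] (or any
#'   data.frame with a `sample_id` column or rownames matching the sample
#'   IDs).
#' @return `expr` with metadata columns in `colData`.
#' @export
joinMetadata <- function(expr, meta) {
  stopifnot(is(expr, "TranscriptExpression"))
  meta <- as.data.frame(meta)
  if ("sample_id" %in% names(meta)) rownames(meta) <- meta$sample_id
  missing <- setdiff(colnames(expr), rownames(meta))
  if (length(missing) > 0) {
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[colnames(expr), , drop = FALSE]
  meta$sample_id <- NULL
  cd <- colData(expr)
  for (v in names(meta)) cd[[v]] <- meta[[v]]
  colData(expr) <- cd
  validObject(expr)
  expr
}

#' Counts-per-million normalization
#'
#' For each sample `s`, `cpm(t, s) = count(t, s) / library_size(s) * 1e6`,
#' where the library size is the column sum over the transcripts present in
#' the supplied matrix.  Because subsetting before normalizing changes the
#' library size, the pipeline always normalizes before gene filtering.
#' A sample with zero total yields all-zero CPM with a warning.
#'
#' @param expr A [TranscriptExpression-class] with a `counts` assay.
#' @return `expr` with an added `cpm` assay.
#' @export
normalizeCPM <- function(expr) {
  stopifnot(is(expr, "TranscriptExpression"))
  cnt <- assay(expr, "counts")
  lib <- colSums(cnt)
  zero <- lib == 0
  if (any(zero)) {
    warning("sample(s) with zero library size get all-zero CPM: ",
            paste(colnames(cnt)[zero], collapse = ", "), call. = FALSE)
    lib[zero] <- 1  # denominators for all-zero columns; numerators are 0
  }
  cpm <- sweep(cnt, 2, lib, "/") * 1e6
  assay(expr, "cpm") <- cpm
  validObject(expr)
  expr
}

#' Relative transcript abundance normalization
#'
#' For each gene `g` and sample `s`,
#' `relative_abundance(t, s) = count(t, s) / sum over transcripts of g of
#' count(., s) * 100` — each transcript's percentage share of its gene's
#' total in that sample.  Genes with a zero total in a sample yield 0 for
#' all their transcripts in that sample.
#'
#' @param expr A [TranscriptExpression-class].
#' @param geneOf Named character vector mapping transcript IDs to gene IDs;
#'   defaults to the `gene_id` column of `rowData(expr)`.  Every transcript
#'   must have a mapping.
#' @return `expr` with an added `relative_abundance` assay (and `gene_id`
#'   stored in `rowData`).
#' @export
normalizeRelativeAbundance <- function(expr, geneOf = NULL) {
  stopifnot(is(expr, "TranscriptExpression"))
  cnt <- assay(expr, "counts")
  if (is.null(geneOf)) {
    rd <- rowData(expr)
    if (!"gene_id" %in% colnames(rd)) {
      stop("no gene mapping: supply geneOf or set rowData(expr)$gene_id",
           call. = FALSE)
    }
    geneOf <- stats::setNames(rd$gene_id, rownames(expr))
  }
  gene <- geneOf[rownames(cnt)]
  orphan <- rownames(cnt)[is.na(gene) | gene == ""]
  if (length(orphan) > 0) {
    stop("transcript(s) without gene mapping: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  gene_tot <- rowsum(cnt, group = gene)           # genes x samples
  den <- gene_tot[gene, , drop = FALSE]           # transcripts x samples
  ra <- cnt / den * 100
  ra[den == 0] <- 0
  dimnames(ra) <- dimnames(cnt)
  assay(expr, "relative_abundance") <- ra
  rowData(expr)$gene_id <- unname(gene)
  validObject(expr)
  expr
}

#' Export the long-form table of a TranscriptExpression
#'
#' Writes [longForm()] output as CSV, TSV or Parquet, dispatched by the
#' output file extension.
#'
#' @param expr A [TranscriptExpression-class].
#' @param path Output path ending in `.csv`, `.tsv` or `.parquet`.
#' @return Invisibly, the path written.
#' @export
exportLongForm <- function(expr, path) {
  lf <- longForm(expr)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(lf, path, row.names = FALSE),
    tsv = utils::write.table(lf, path, sep = "\t", row.names = FALSE,
                             quote = FALSE),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("writing Parquet requires the 'arrow' package", call. = FALSE)
      }
      arrow::write_parquet(lf, path)
    },
    stop("unsupported export extension '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
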