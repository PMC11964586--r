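#' @include accessors.R
NULL

GTF_ATTR_ORDER <- c("gene_id", "gene_name", "transcript_id",
                    "transcript_name", "transcript_biotype", "exon_number")

# Parse one GTF attribute column into a named character vector.
# Lenient mode accepts both `key "value";` and `key value;` pairs (ENSEMBL
# vs RefSeq dialects); strict mode requires quoted values.
parseAttributes <- function(attr, lenient, lineno) {
  tokens <- strsplit(attr, ";", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  tokens <- tokens[tokens != ""]
  out <- character(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec('^(\\S+)\\s+"(.*)"$', tok))[[1]]
    if (length(m) == 0 && lenient) {
      m <- regmatches(tok, regexec("^(\\S+)\\s+(.*)$", tok))[[1]]
    }
    if (length(m) == 0) {
      stop(sprintf("malformed GTF attribute on line %d: '%s'", lineno, tok),
           call. = FALSE)
    }
    out[m[2]] <- m[3]
  }
  out
}

#' Read a GTF annotation file into a FeatureTable
#'
#' Parses tab-separated 9-column GTF (1-based inclusive coordinates,
#' `key "value";` attributes, `#` comments), keeping only the requested
#' feature kinds.  The attributes `gene_id`, `gene_name`, `transcript_id`,
#' `transcript_name`, `transcript_biotype` and `exon_number` are extracted;
#' unknown keys are ignored.  A missing `gene_name` falls back to `gene_id`
#' and a missing `transcript_name` to `transcript_id`, so both are never
#' empty on exon/CDS records.  Records whose strand is not `+` or `-` are
#' rejected: exon numbering and intron direction are strand-dependent, so a
#' silent default would mislabel.
#'
#' @param path Path to a GTF file.
#' @param keepKinds Character vector of feature kinds to retain (third GTF
#'   column); defaults to `c("exon", "CDS")`.
#' @param attributeMode `"lenient"` (default) accepts both quoted and
#'   unquoted attribute values; `"strict"` requires the quoted ENSEMBL form.
#' @return A [FeatureTable-class]; record order equals file line order
#'   within the kept kinds.  Duplicate identical records are dropped with a
#'   warning.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tdemo\texon\t100\t200\t.\t+\t.",
#'                  'gene_id "G1"; transcript_id "T1";', sep = "\t"), gtf)
#' ft <- readGTF(gtf)
#' featureFrame(ft)
#' @export
readGTF <- function(path, keepKinds = c("exon", "CDS"),
                    attributeMode = c("lenient", "strict")) {
  attributeMode <- match.arg(attributeMode)
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0) {
    stop("no features retained: file '", path, "' has no feature lines",
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9)) {
    bad <- which(nfield != 9)[1]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated columns, found %d",
                 lineno[bad], nfield[bad]), call. = FALSE)
  }
  feat <- vapply(fields, `[`, character(1), 3)
  sel <- feat %in% keepKinds
  if (!any(sel)) {
    stop("no features retained: no records of kind(s) ",
         paste(keepKinds, collapse = ", "), " in '", path, "'", call. = FALSE)
  }
  fields <- fields[sel]
  lineno <- lineno[sel]
  col <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.integer(col(4)))
  end <- suppressWarnings(as.integer(col(5)))
  if (any(is.na(start)) || any(is.na(end))) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", lineno[bad]),
         call. = FALSE)
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    stop(sprintf("invalid record on line %d: start %d > end %d",
                 lineno[bad], start[bad], end[bad]), call. = FALSE)
  }
  strand <- col(7)
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    stop(sprintf(
      "record on line %d has strand '%s'; only '+' or '-' are supported (strand determines exon numbering and intron direction)",
      lineno[bad], strand[bad]), call. = FALSE)
  }
  lenient <- attributeMode == "lenient"
  attrs <- mapply(parseAttributes, col(9), lenient, lineno, SIMPLIFY = FALSE)
  pick <- function(key) {
    vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
           character(1), USE.NAMES = FALSE)
  }
  type <- vapply(fields, `[`, character(1), 3)
  df <- data.frame(
    seqname = col(1),
    source = ifelse(col(2) == ".", NA_character_, col(2)),
    type = type,
    start = start, end = end, strand = strand,
    gene_id = pick("gene_id"),
    gene_name = pick("gene_name"),
    transcript_id = pick("transcript_id"),
    transcript_name = pick("transcript_name"),
    transcript_biotype = pick("transcript_biotype"),
    exon_number = suppressWarnings(as.integer(pick("exon_number"))),
    stringsAsFactors = FALSE
  )
  ec <- df$type %in% c("exon", "CDS")
  no_tx <- ec & (is.na(df$transcript_id) | df$transcript_id == "")
  if (any(no_tx)) {
    stop(sprintf("validation error on line %d: %s record lacks transcript_id",
                 lineno[which(no_tx)[1]], df$type[which(no_tx)[1]]), call. = FALSE)
  }
  no_gene <- ec & (is.na(df$gene_id) | df$gene_id == "")
  if (any(no_gene)) {
    stop(sprintf("validation error on line %d: %s record lacks gene_id",
                 lineno[which(no_gene)[1]], df$type[which(no_gene)[1]]), call. = FALSE)
  }
  # missing-name fallbacks: names are never empty downstream
  fb <- is.na(df$gene_name) | df$gene_name == ""
  df$gene_name[fb] <- df$gene_id[fb]
  has_tx <- !is.na(df$transcript_id) & df$transcript_id != ""
  fb <- has_tx & (is.na(df$transcript_name) | df$transcript_name == "")
  df$transcript_name[fb] <- df$transcript_id[fb]
  key <- paste(df$transcript_id, df$type, df$start, df$end, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    warning(sprintf("dropped %d duplicate identical record(s) while reading '%s'",
                    sum(dup), path), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  FeatureTable(df, provenance = list(path = path, keep_kinds = keepKinds,
                                     attribute_mode = attributeMode))
}

#' Write a FeatureTable to a GTF file
#'
#' Emits valid 9-column GTF with attributes serialized in a fixed key order
#' (`gene_id`, `gene_name`, `transcript_id`, `transcript_name`,
#' `transcript_biotype`, `exon_number`), omitting attributes that are
#' missing.  `readGTF(writeGTF(x))` reproduces `x` record for record.
#'
#' @param x A non-empty [FeatureTable-class].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
writeGTF <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  if (length(x) == 0) stop("cannot write an empty FeatureTable", call. = FALSE)
  df <- featureFrame(x)
  attrs <- vapply(seq_len(nrow(df)), function(i) {
    parts <- character(0)
    for (key in GTF_ATTR_ORDER) {
      val <- df[[key]][i]
      if (!is.na(val) && val != "") {
        parts <- c(parts, sprintf('%s "%s";', key, val))
      }
    }
    paste(parts, collapse = " ")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   df$seqname,
                   ifelse(is.na(df$source), ".", df$source),
                   df$type, as.integer(df$start), as.integer(df$end),
                   df$strand, attrs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Compare transcript IDs between annotation and expression data
#'
#' Pure report: partitions the transcript identifiers into those shared by
#' both inputs, those only in the annotation, and those only in the
#' expression matrix.  Raises no error itself; callers decide what a
#' mismatch means.
#'
#' @param annotation A non-empty [FeatureTable-class].
#' @param expr A non-empty [TranscriptExpression-class].
#' @return A list with character vectors `shared`, `annotationOnly`,
#'   `expressionOnly` (disjoint, sorted).
#' @export
checkExpressionConsistency <- function(annotation, expr) {
  stopifnot(is(annotation, "FeatureTable"), is(expr, "TranscriptExpression"))
  if (length(annotation) == 0) stop("annotation is empty", call. = FALSE)
  if (nrow(expr) == 0) stop("expression table is empty", call. = FALSE)
  m <- mcols(annotation@records)
  ann_tx <- unique(m$transcript_id[!is.na(m$transcript_id) & m$transcript_id != ""])
  expr_tx <- rownames(expr)
  list(
    shared = sort(intersect(ann_tx, expr_tx)),
    annotationOnly = sort(setdiff(ann_tx, expr_tx)),
    expressionOnly = sort(setdiff(expr_tx, ann_tx))
  )
}
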