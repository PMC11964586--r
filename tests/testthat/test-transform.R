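test_that("gene filtering restricts both annotation and expression", {
  ann <- toyAnnotation(exonRow("T1", 1, 10, gene = "G1"),
                       exonRow("T2", 20, 30, gene = "G1"),
                       exonRow("T3", 40, 50, gene = "G2"))
  cnt <- matrix(1:6, 3, 2, dimnames = list(c("T1", "T2", "T3"), c("s1", "s2")))
  expr <- TranscriptExpression(cnt)
  flt <- filterGene(ann, expr, "G1")
  expect_setequal(featureFrame(flt$annotation)$transcript_id, c("T1", "T2"))
  expect_setequal(rownames(flt$expression), c("T1", "T2"))
})

test_that("filtering by symbol equals filtering by ID, and typos get suggestions", {
  fx <- generateFixture(fixtureConfig(seed = 2), tempfile("fx"))
  ann <- readGTF(fx$gtf)
  by_id <- filterGene(ann, NULL, "GENE002")$annotation
  by_name <- filterGene(ann, NULL, "Gene2")$annotation
  expect_equal(featureFrame(by_id), featureFrame(by_name))

  expect_error(filterGene(ann, NULL, "GENE00"), "did you mean.*GENE001")
  expect_error(filterGene(ann, NULL, "gene002"), "not found")
  expect_equal(featureFrame(filterGene(ann, NULL, "gene002",
                                       ignoreCase = TRUE)$annotation),
               featureFrame(by_id))
})

test_that("ranking sorts by the reduced metric with lexicographic tie-break", {
  cnt <- matrix(c(10, 30, 20, 10, 30, 20), 3, 2,
                dimnames = list(c("T1", "T2", "T3"), c("s1", "s2")))
  expr <- TranscriptExpression(cnt)
  expect_equal(rankAndSelect(expr, "raw_count", "mean", 2), c("T2", "T3"))

  tie <- TranscriptExpression(matrix(c(5, 5), 2, 1,
                                     dimnames = list(c("T2", "T1"), "s1")))
  expect_equal(rankAndSelect(tie, "raw_count", "mean", 2), c("T1", "T2"))

  expect_warning(all3 <- rankAndSelect(expr, "raw_count", "mean", 99),
                 "exceeds")
  expect_length(all3, 3)
  expect_error(rankAndSelect(expr, "cpm", "mean", 2), "not been computed")
  expect_error(rankAndSelect(expr, "raw_count", "mean", 0), "positive integer")
})

test_that("fixture ranking matches the generator's own bookkeeping", {
  fx <- generateFixture(fixtureConfig(seed = 13), tempfile("fx"))
  ann <- readGTF(fx$gtf)
  expr <- readExpression(fx$counts)
  for (g in names(fx$truth$genes)) {
    tr <- fx$truth$genes[[g]]
    sub <- filterGene(ann, expr, g)$expression
    expect_equal(rankAndSelect(sub, "raw_count", "mean", nrow(sub)),
                 unlist(tr$expected_rank))
  }
})

test_that("exon numbering follows transcription order on each strand", {
  plus <- toyAnnotation(exonRow("T1", 100, 200), exonRow("T1", 300, 400))
  dfp <- featureFrame(addExonNumber(plus))
  expect_equal(dfp$exon_number, c(1L, 2L))

  minus <- toyAnnotation(exonRow("T1", 100, 200, strand = "-"),
                         exonRow("T1", 300, 400, strand = "-"))
  dfm <- featureFrame(addExonNumber(minus))
  expect_equal(dfm$exon_number, c(2L, 1L))
})

test_that("CDS records inherit the containing exon's number", {
  ann <- toyAnnotation(exonRow("T1", 100, 200, strand = "-"),
                       exonRow("T1", 300, 400, strand = "-"),
                       exonRow("T1", 320, 380, type = "CDS", strand = "-"))
  df <- featureFrame(addExonNumber(ann))
  expect_equal(df$exon_number[df$type == "CDS"], 1L)

  bad <- toyAnnotation(exonRow("T1", 100, 200),
                       exonRow("T1", 300, 400),
                       exonRow("T1", 150, 350, type = "CDS"))
  expect_error(addExonNumber(bad), "not contained in any")
})

test_that("flipping strand exactly reverses every transcript's numbering", {
  fx <- generateFixture(fixtureConfig(seed = 21), tempfile("fx"))
  ann <- addExonNumber(readGTF(fx$gtf))
  df <- featureFrame(ann)
  flipped_df <- featureFrame(ann)
  flipped_df$strand <- ifelse(flipped_df$strand == "+", "-", "+")
  flipped <- featureFrame(addExonNumber(FeatureTable(flipped_df)))
  for (tx in unique(df$transcript_id[df$type == "exon"])) {
    a <- df[df$type == "exon" & df$transcript_id == tx, ]
    b <- flipped[flipped$type == "exon" & flipped$transcript_id == tx, ]
    n <- nrow(a)
    expect_equal(b$exon_number, n + 1L - a$exon_number)
  }
})

test_that("introns tile the space between consecutive exons", {
  ann <- toyAnnotation(exonRow("T1", 100, 200), exonRow("T1", 300, 400),
                       exonRow("T1", 500, 600))
  df <- featureFrame(toIntron(ann))
  introns <- df[df$type == "intron", ]
  expect_equal(introns$start, c(201, 401))
  expect_equal(introns$end, c(299, 499))

  single <- toyAnnotation(exonRow("T1", 100, 200))
  expect_equal(sum(featureFrame(toIntron(single))$type == "intron"), 0)

  adjacent <- toyAnnotation(exonRow("T1", 100, 200), exonRow("T1", 201, 300))
  expect_equal(sum(featureFrame(toIntron(adjacent))$type == "intron"), 0)

  overlap <- toyAnnotation(exonRow("T1", 100, 200), exonRow("T1", 150, 300))
  expect_error(toIntron(overlap), "overlapping exons.*T1")
})

test_that("exon plus intron lengths always sum to the transcript span", {
  fx <- generateFixture(fixtureConfig(seed = 17), tempfile("fx"))
  df <- featureFrame(toIntron(readGTF(fx$gtf)))
  for (tx in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tx & df$type %in% c("exon", "intron"), ]
    ex <- sub[sub$type == "exon", ]
    span <- max(ex$end) - min(ex$start) + 1
    expect_identical(sum(sub$end - sub$start + 1), span)
  }
})

test_that("fixture truth introns equal the derived introns", {
  fx <- generateFixture(fixtureConfig(seed = 23), tempfile("fx"))
  df <- featureFrame(toIntron(readGTF(fx$gtf)))
  for (g in fx$truth$genes) {
    for (tx in g$transcripts) {
      mine <- df[df$transcript_id == tx$transcript_id & df$type == "intron", ]
      truth <- matrix(unlist(tx$introns), ncol = 2)
      expect_equal(nrow(mine), nrow(truth))
      if (nrow(truth) > 0) {
        expect_equal(mine$start, truth[, 1])
        expect_equal(mine$end, truth[, 2])
      }
    }
  }
})

test_that("the worked two-exon example maps to capped display coordinates", {
  ann <- toyAnnotation(exonRow("T1", 1, 100), exonRow("T1", 10001, 10100))
  gm <- buildGapMap(ann, cap = 100)
  disp <- featureFrame(applyGapMap(gm, ann))
  expect_equal(disp$start, c(1, 201))
  expect_equal(disp$end, c(100, 300))
  # per-base oracle agrees at the boundaries
  oracle <- brutePerBaseMap(c(1, 10001), c(100, 10100), 100)
  expect_identical(mapToDisplay(gm, c(1, 100, 10001, 10100)),
                   oracle(c(1, 100, 10001, 10100)))
})

test_that("gaps at or below the cap are left untouched", {
  ann <- toyAnnotation(exonRow("T1", 1, 100), exonRow("T1", 150, 250))
  gm <- buildGapMap(ann, cap = 100)
  disp <- featureFrame(applyGapMap(gm, ann))
  expect_equal(disp$start, c(1, 150))
  expect_equal(disp$end, c(100, 250))
})

test_that("an exon of one transcript inside another's intron keeps that region covered", {
  ann <- toyAnnotation(exonRow("T1", 1, 100), exonRow("T1", 20001, 20100),
                       exonRow("T2", 9001, 9100))
  gm <- buildGapMap(ann, cap = 100)
  seg <- gapSegments(gm)
  expect_equal(nrow(seg), 5)       # exon, gap, embedded exon, gap, exon
  expect_equal(sum(seg$covered), 3)
  # both flanking sub-gaps are long and each compresses to exactly cap
  gaps <- seg[!seg$covered, ]
  expect_equal(gaps$display_end - gaps$display_start + 1, c(100, 100))
  # T1's intron spans the embedded exon: display length = 100 + 100 + 100
  withIntrons <- toIntron(ann)
  disp <- featureFrame(applyGapMap(gm, withIntrons))
  intr <- disp[disp$type == "intron" & disp$transcript_id == "T1", ]
  expect_equal(intr$end - intr$start + 1, 300)
})

test_that("gap map construction validates its inputs", {
  ann <- toyAnnotation(exonRow("T1", 1, 100))
  expect_error(buildGapMap(ann, cap = 0), "positive")
  expect_error(buildGapMap(ann, cap = 10.5), "whole number")
  expect_error(buildGapMap(ann, transcripts = "TX_ABSENT"), "no exon records")
  two_chr <- rbind(featureFrame(toyAnnotation(exonRow("T1", 1, 100))),
                   within(featureFrame(toyAnnotation(exonRow("T2", 1, 100))),
                          seqname <- "chr2"))
  expect_error(buildGapMap(FeatureTable(two_chr)), "multiple seqnames")
})

test_that("a cap at least as long as every gap yields the identity map", {
  ann <- toyAnnotation(exonRow("T1", 1, 100), exonRow("T1", 10001, 10100))
  gm <- buildGapMap(ann, cap = 20000)
  disp <- featureFrame(applyGapMap(gm, ann))
  expect_equal(disp$start, c(1, 10001))
  expect_equal(disp$end, c(100, 10100))
})

test_that("records outside the map domain are rejected", {
  ann <- toyAnnotation(exonRow("T1", 100, 200))
  gm <- buildGapMap(ann, cap = 100)
  outside <- toyAnnotation(exonRow("T1", 50, 150))
  expect_error(applyGapMap(gm, outside), "outside the map domain")
})

test_that("random loci match the per-base oracle at every feature boundary", {
  set.seed(101)
  for (it in 1:40) {
    ann <- toIntron(randomLocus())
    df <- featureFrame(ann)
    ex <- df[df$type == "exon", ]
    cap <- sample(c(50, 100, 500), 1)
    gm <- buildGapMap(ann, cap = cap)
    oracle <- brutePerBaseMap(ex$start, ex$end, cap)
    disp <- featureFrame(applyGapMap(gm, ann))
    expect_identical(as.numeric(disp$start), oracle(df$start))
    expect_identical(as.numeric(disp$end), oracle(df$end + 1) - 1)
    # exon display length preserved exactly
    dex <- disp[disp$type == "exon", ]
    expect_identical(dex$end - dex$start, ex$end - ex$start)
    # monotone over sampled in-exon positions
    pos <- sort(unique(unlist(mapply(function(s, e) s:min(e, s + 50),
                                     ex$start, ex$end, SIMPLIFY = FALSE))))
    expect_true(all(diff(mapToDisplay(gm, pos)) > 0))
  }
})

test_that("rescaling an already-rescaled locus changes nothing", {
  set.seed(77)
  for (it in 1:10) {
    ann <- randomLocus()
    gm <- buildGapMap(ann, cap = 100)
    once <- applyGapMap(gm, ann)
    gm2 <- buildGapMap(once, cap = 100)
    twice <- applyGapMap(gm2, once)
    expect_equal(featureFrame(twice)$start, featureFrame(once)$start)
    expect_equal(featureFrame(twice)$end, featureFrame(once)$end)
  }
})
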