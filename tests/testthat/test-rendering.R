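makeToyFigureParts <- function(seed = 1) {
  ann <- toyAnnotation(exonRow("T1", 100, 200), exonRow("T1", 1001, 1100),
                       exonRow("T1", 120, 180, type = "CDS"),
                       exonRow("T2", 100, 200))
  ann <- toIntron(addExonNumber(ann))
  gm <- buildGapMap(ann, cap = 100)
  disp <- applyGapMap(gm, ann)
  cnt <- matrix(c(1:8, 8:1), nrow = 2, byrow = TRUE,
                dimnames = list(c("T1", "T2"), paste0("s", 1:8)))
  expr <- joinMetadata(TranscriptExpression(cnt),
                       data.frame(sample_id = paste0("s", 1:8),
                                  condition = rep(c("AD", "control"), each = 4)))
  list(disp = disp, expr = expr, rowOrder = c("T1", "T2"), seed = seed)
}

test_that("CDS boxes are exactly twice the height of exon boxes", {
  p <- makeToyFigureParts()
  panel <- makeStructurePanel(p$disp, p$rowOrder)
  sh <- panel$shapes
  hx <- sh$y1 - sh$y0
  expect_equal(unique(hx[sh$kind == "CDS"]) / unique(hx[sh$kind == "exon"]), 2)
})

test_that("a transcript without CDS renders only low boxes", {
  ann <- toIntron(addExonNumber(toyAnnotation(exonRow("T1", 1, 50),
                                              exonRow("T1", 100, 150))))
  panel <- makeStructurePanel(ann, "T1")
  expect_false("CDS" %in% panel$shapes$kind)
  expect_equal(sum(panel$shapes$kind == "exon"), 2)
})

test_that("hover payloads carry all six fields with genomic lengths", {
  p <- makeToyFigureParts()
  panel <- makeStructurePanel(p$disp, p$rowOrder)
  ex <- panel$shapes[panel$shapes$kind == "exon", ]
  for (f in expectedSixFields) expect_true(all(grepl(f, ex$hover, fixed = TRUE)))
  # display-space gap compression must not leak into the hover length
  second_exon <- ex[grepl("Start: 1001", ex$hover), ]
  expect_match(second_exon$hover, "Length: 100 bp")
  intr <- panel$shapes[panel$shapes$kind == "intron", ]
  expect_match(intr$hover, "Length: 800 bp")  # genomic 201..1000
})

test_that("hover length is genomic end - start + 1", {
  ann <- toIntron(addExonNumber(toyAnnotation(exonRow("T1", 201, 299))))
  panel <- makeStructurePanel(ann, "T1")
  expect_match(panel$shapes$hover[1], "Length: 99 bp")
})

test_that("strand arrows point along the transcription direction", {
  minus <- toyAnnotation(exonRow("T1", 1, 100, strand = "-"),
                         exonRow("T1", 2001, 2100, strand = "-"))
  minus <- toIntron(addExonNumber(minus))
  panel <- makeStructurePanel(minus, "T1", arrowSpacing = 300)
  expect_gt(nrow(panel$arrows), 0)
  expect_true(all(panel$arrows$direction == "left"))

  plus <- toyAnnotation(exonRow("T1", 1, 100), exonRow("T1", 2001, 2100))
  plus <- toIntron(addExonNumber(plus))
  expect_true(all(makeStructurePanel(plus, "T1",
                                     arrowSpacing = 300)$arrows$direction == "right"))
})

test_that("a row-order transcript missing from the annotation is an error", {
  p <- makeToyFigureParts()
  expect_error(makeStructurePanel(p$disp, c("T1", "T_MISSING")),
               "no exon records.*T_MISSING")
})

test_that("box statistics reproduce the hand-computed Tukey example", {
  cnt <- matrix(c(1, 2, 3, 4, 100), 1, 5,
                dimnames = list("T1", paste0("s", 1:5)))
  expr <- joinMetadata(TranscriptExpression(cnt),
                       data.frame(sample_id = paste0("s", 1:5), condition = "g"))
  bs <- computeBoxStats(expr, "raw_count", "T1", "condition")
  expect_equal(bs$median, 3)
  expect_equal(bs$lower_quartile, 2)
  expect_equal(bs$upper_quartile, 4)
  expect_equal(bs$iqr, 2)
  expect_equal(bs$fence_high, 7)
  expect_equal(bs$whisker_high, 4)
  expect_equal(bs$outliers[[1]], 100)
})

test_that("constant samples give a degenerate box with no outliers", {
  cnt <- matrix(5, 1, 4, dimnames = list("T1", paste0("s", 1:4)))
  expr <- joinMetadata(TranscriptExpression(cnt),
                       data.frame(sample_id = paste0("s", 1:4), condition = "g"))
  bs <- computeBoxStats(expr, "raw_count", "T1", "condition")
  expect_equal(bs$median, 5)
  expect_equal(bs$lower_quartile, 5)
  expect_equal(bs$upper_quartile, 5)
  expect_length(bs$outliers[[1]], 0)
})

test_that("two groups of four give one four-point box per group", {
  p <- makeToyFigureParts()
  bs <- computeBoxStats(p$expr, "raw_count", p$rowOrder, "condition")
  expect_equal(nrow(bs), 4)   # 2 transcripts x 2 groups
  expect_true(all(bs$n == 4))
  expect_error(computeBoxStats(p$expr, "raw_count", p$rowOrder, "nope"),
               "grouping variable 'nope'")
})

test_that("box statistics agree with the first-principles oracle", {
  set.seed(300)
  for (it in 1:50) {
    n <- sample(3:50, 1)
    x <- as.numeric(stats::rnbinom(n, mu = 80, size = 1))
    cnt <- matrix(x, 1, n, dimnames = list("T1", paste0("s", seq_len(n))))
    expr <- joinMetadata(TranscriptExpression(cnt),
                         data.frame(sample_id = paste0("s", seq_len(n)),
                                    condition = "g"))
    bs <- computeBoxStats(expr, "raw_count", "T1", "condition")
    oracle <- bruteBoxStats(x)
    expect_identical(bs$median, oracle$median)
    expect_identical(bs$lower_quartile, oracle$lower_quartile)
    expect_identical(bs$upper_quartile, oracle$upper_quartile)
    expect_identical(bs$whisker_low, oracle$whisker_low)
    expect_identical(bs$whisker_high, oracle$whisker_high)
    expect_identical(sort(bs$outliers[[1]]), oracle$outliers)
    # every point is classified exactly once
    expect_identical(length(bs$points[[1]]),
                     length(oracle$outliers) +
                       sum(x >= oracle$fence_low & x <= oracle$fence_high))
  }
})

test_that("whiskers terminate at data values within the fences", {
  set.seed(301)
  for (it in 1:25) {
    x <- round(stats::rlnorm(sample(5:30, 1), 3, 1), 3)
    cnt <- matrix(x, 1, length(x),
                  dimnames = list("T1", paste0("s", seq_along(x))))
    expr <- joinMetadata(TranscriptExpression(cnt),
                         data.frame(sample_id = paste0("s", seq_along(x)),
                                    condition = "g"))
    bs <- computeBoxStats(expr, "raw_count", "T1", "condition")
    expect_true(bs$whisker_low %in% x || bs$whisker_low == bs$lower_quartile)
    expect_true(bs$whisker_high %in% x || bs$whisker_high == bs$upper_quartile)
    expect_gte(bs$whisker_low, bs$fence_low)
    expect_lte(bs$whisker_high, bs$fence_high)
  }
})

test_that("assembled figures share one row order across all panels", {
  p <- makeToyFigureParts()
  struct <- makeStructurePanel(p$disp, p$rowOrder)
  ep <- makeExpressionPanel(p$expr, "raw_count", p$rowOrder, "condition",
                            jitterSeed = p$seed)
  fig <- assembleFigure(struct, list(ep), p$rowOrder, title = "toy")
  expect_s4_class(fig, "FigureSpec")
  expect_equal(rowOrder(fig), p$rowOrder)
  # identical vertical position of each transcript in every panel
  expect_identical(struct$ypos, ep$ypos)
  expect_equal(legendGroups(fig), c("AD", "control"))

  # structure-only assembly is valid
  solo <- assembleFigure(struct, list(), p$rowOrder)
  expect_length(solo@panels, 0)

  bad <- makeExpressionPanel(p$expr, "raw_count", rev(p$rowOrder), "condition")
  expect_error(assembleFigure(struct, list(bad), p$rowOrder), "assembly error")
})

test_that("every expression trace belongs to exactly one legend group", {
  p <- makeToyFigureParts()
  ep <- makeExpressionPanel(p$expr, "raw_count", p$rowOrder, "condition")
  expect_true(all(ep$points$group %in% ep$groups))
  expect_true(all(ep$boxes$group %in% ep$groups))
  expect_equal(sort(unique(ep$boxes$group)), sort(ep$groups))
})

test_that("jitter is deterministic under a fixed seed and leaves the RNG alone", {
  p <- makeToyFigureParts()
  set.seed(9999)
  before <- stats::runif(1)
  set.seed(9999)
  e1 <- makeExpressionPanel(p$expr, "raw_count", p$rowOrder, "condition",
                            jitterSeed = 4)
  after <- stats::runif(1)
  expect_identical(before, after)  # caller's RNG stream undisturbed
  e2 <- makeExpressionPanel(p$expr, "raw_count", p$rowOrder, "condition",
                            jitterSeed = 4)
  expect_identical(e1$points$y, e2$points$y)
  e3 <- makeExpressionPanel(p$expr, "raw_count", p$rowOrder, "condition",
                            jitterSeed = 5)
  expect_false(identical(e1$points$y, e3$points$y))
})
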