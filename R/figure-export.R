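#' @include rendering.R
NULL

# -- small SVG helpers -------------------------------------------------------

svgEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmt <- function(x) {
  out <- sprintf("%.2f", x)
  sub("^-0\\.00$", "0.00", out)
}

fmtTick <- function(x) formatC(x, format = "fg", digits = 8)

# Geometry shared by the SVG and base-graphics renderers.
figureLayout <- function(fig, width = 1200, rowHeight = 70) {
  n <- length(fig@rowOrder)
  has_struct <- length(fig@structure) > 0
  npan <- length(fig@panels)
  weights <- c(if (has_struct) 2 else NULL, rep(1, npan))
  left <- 150; right <- if (length(fig@legendGroups) > 0) 150 else 30
  top <- 70; bottom <- 55; gapx <- 45
  plot_w <- width - left - right - gapx * (length(weights) - 1)
  pw <- plot_w * weights / sum(weights)
  x0 <- left + c(0, cumsum(pw[-length(pw)] + gapx))
  plot_h <- n * rowHeight
  height <- top + plot_h + bottom
  list(n = n, width = width, height = height, top = top, bottom = bottom,
       plot_h = plot_h, panel_x0 = x0, panel_w = pw, has_struct = has_struct)
}

ypix <- function(lay, y) lay$top + (lay$n + 0.5 - y) / lay$n * lay$plot_h

padRange <- function(r) {
  span <- max(r[2] - r[1], 1)
  c(r[1] - 0.02 * span, r[2] + 0.02 * span)
}

xpixFun <- function(lay, ipanel, xrange) {
  xr <- padRange(xrange)
  x0 <- lay$panel_x0[ipanel]
  w <- lay$panel_w[ipanel]
  function(x) x0 + (x - xr[1]) / (xr[2] - xr[1]) * w
}

panelAxisSVG <- function(lay, ipanel, xrange, label) {
  xp <- xpixFun(lay, ipanel, xrange)
  x0 <- lay$panel_x0[ipanel]
  x1 <- x0 + lay$panel_w[ipanel]
  yb <- lay$top + lay$plot_h
  out <- c(sprintf('<path class="frame" d="M %s %s H %s V %s H %s Z" fill="none" stroke="#cccccc"/>',
                   fmt(x0), fmt(lay$top), fmt(x1), fmt(yb), fmt(x0)))
  ticks <- pretty(xrange, n = 4)
  ticks <- ticks[ticks >= padRange(xrange)[1] & ticks <= padRange(xrange)[2]]
  for (t in ticks) {
    tx <- xp(t)
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888"/>',
              fmt(tx), fmt(yb), fmt(tx), fmt(yb + 5)),
      sprintf('<text x="%s" y="%s" text-anchor="middle" class="tick">%s</text>',
              fmt(tx), fmt(yb + 18), svgEsc(fmtTick(t))))
  }
  c(out, sprintf('<text x="%s" y="%s" text-anchor="middle" class="axis-label">%s</text>',
                 fmt((x0 + x1) / 2), fmt(yb + 38), svgEsc(label)))
}

structurePanelSVG <- function(fig, lay, ipanel) {
  p <- fig@structure
  xp <- xpixFun(lay, ipanel, p$xRange)
  out <- sprintf('<text x="%s" y="%s" text-anchor="middle" class="panel-title">%s</text>',
                 fmt(lay$panel_x0[ipanel] + lay$panel_w[ipanel] / 2),
                 fmt(lay$top - 12), svgEsc(p$title))
  sh <- p$shapes
  # introns (lines) first so boxes overdraw them
  for (i in order(match(sh$kind, c("intron", "exon", "CDS")))) {
    r <- sh[i, ]
    if (r$kind == "intron") {
      out <- c(out, sprintf(
        '<line class="hoverable intron" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" data-hover="%s"/>',
        fmt(xp(r$x0)), fmt(ypix(lay, r$y0)), fmt(xp(r$x1)), fmt(ypix(lay, r$y1)),
        svgEsc(r$hover)))
    } else {
      fill <- if (r$kind == "CDS") "#2c7fb8" else "#a6bddb"
      out <- c(out, sprintf(
        '<rect class="hoverable %s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#1c3d5a" stroke-width="0.5" data-hover="%s"/>',
        r$kind, fmt(xp(r$x0)), fmt(ypix(lay, r$y1)),
        fmt(xp(r$x1) - xp(r$x0)), fmt(ypix(lay, r$y0) - ypix(lay, r$y1)),
        fill, svgEsc(r$hover)))
    }
  }
  if (nrow(p$arrows) > 0) {
    for (i in seq_len(nrow(p$arrows))) {
      a <- p$arrows[i, ]
      x <- xp(a$x); y <- ypix(lay, a$y)
      d <- if (a$direction == "right") {
        sprintf("M %s %s L %s %s L %s %s", fmt(x - 3), fmt(y - 3.5),
                fmt(x + 3), fmt(y), fmt(x - 3), fmt(y + 3.5))
      } else {
        sprintf("M %s %s L %s %s L %s %s", fmt(x + 3), fmt(y - 3.5),
                fmt(x - 3), fmt(y), fmt(x + 3), fmt(y + 3.5))
      }
      out <- c(out, sprintf('<path class="arrow" d="%s" fill="none" stroke="#444444"/>', d))
    }
  }
  c(out, panelAxisSVG(lay, ipanel, p$xRange,
                      sprintf("Display position (%s)", p$chrom)))
}

expressionPanelSVG <- function(fig, lay, ipanel, p) {
  xp <- xpixFun(lay, ipanel, p$xRange)
  pal <- fig@config$palette
  out <- sprintf('<text x="%s" y="%s" text-anchor="middle" class="panel-title">%s</text>',
                 fmt(lay$panel_x0[ipanel] + lay$panel_w[ipanel] / 2),
                 fmt(lay$top - 12), svgEsc(p$title))
  b <- p$boxes
  for (i in seq_len(nrow(b))) {
    r <- b[i, ]
    if (is.na(r$median)) next
    col <- pal[[r$group]]
    gy <- r$y
    y0 <- ypix(lay, gy - r$box_half); y1 <- ypix(lay, gy + r$box_half)
    yc <- ypix(lay, gy)
    hov <- sprintf("Transcript: %s<br>Group: %s<br>n = %d<br>Median: %s<br>Q1: %s<br>Q3: %s<br>Whiskers: [%s, %s]",
                   r$transcript_id, r$group, r$n, fmtTick(r$median),
                   fmtTick(r$lower_quartile), fmtTick(r$upper_quartile),
                   fmtTick(r$whisker_low), fmtTick(r$whisker_high))
    grp <- svgEsc(r$group)
    # whiskers with caps
    out <- c(out,
      sprintf('<line data-group="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              grp, fmt(xp(r$whisker_low)), fmt(yc), fmt(xp(r$lower_quartile)), fmt(yc), col),
      sprintf('<line data-group="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              grp, fmt(xp(r$upper_quartile)), fmt(yc), fmt(xp(r$whisker_high)), fmt(yc), col),
      sprintf('<line data-group="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              grp, fmt(xp(r$whisker_low)), fmt(yc - 4), fmt(xp(r$whisker_low)), fmt(yc + 4), col),
      sprintf('<line data-group="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              grp, fmt(xp(r$whisker_high)), fmt(yc - 4), fmt(xp(r$whisker_high)), fmt(yc + 4), col),
      sprintf('<path class="hoverable box" data-group="%s" d="M %s %s H %s V %s H %s Z" fill="%s" fill-opacity="0.45" stroke="%s" data-hover="%s"/>',
              grp, fmt(xp(r$lower_quartile)), fmt(y1), fmt(xp(r$upper_quartile)),
              fmt(y0), fmt(xp(r$lower_quartile)), col, col, svgEsc(hov)),
      sprintf('<line data-group="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
              grp, fmt(xp(r$median)), fmt(y0), fmt(xp(r$median)), fmt(y1), col))
  }
  pts <- p$points
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, ]
    out <- c(out, sprintf(
      '<circle class="hoverable point" data-group="%s" cx="%s" cy="%s" r="3" fill="%s" stroke="#ffffff" stroke-width="0.5" data-hover="%s"/>',
      svgEsc(r$group), fmt(xp(r$value)), fmt(ypix(lay, r$y)),
      pal[[r$group]], svgEsc(r$hover)))
  }
  c(out, panelAxisSVG(lay, ipanel, p$xRange, p$title))
}

# Render a FigureSpec to SVG markup (character vector of lines).
figureToSVG <- function(fig, width = 1200, rowHeight = 70, standalone = FALSE) {
  validObject(fig)
  lay <- figureLayout(fig, width, rowHeight)
  head <- sprintf('<svg %sid="figure" viewBox="0 0 %d %d" width="%d" height="%d" font-family="Helvetica, Arial, sans-serif">',
                  if (standalone) 'xmlns="http://www.w3.org/2000/svg" ' else "",
                  lay$width, round(lay$height), lay$width, round(lay$height))
  body <- c(
    sprintf('<text x="%s" y="%s" text-anchor="middle" class="fig-title" font-size="16">%s</text>',
            fmt(lay$width / 2), fmt(28), svgEsc(fig@title))
  )
  # transcript row labels, left of the first panel
  for (i in seq_along(fig@rowOrder)) {
    y <- ypix(lay, lay$n - i + 1)
    body <- c(body, sprintf(
      '<text x="%s" y="%s" text-anchor="end" class="row-label" font-size="12">%s</text>',
      fmt(lay$panel_x0[1] - 8), fmt(y + 4), svgEsc(fig@rowOrder[i])))
  }
  ipanel <- 0
  if (lay$has_struct) {
    ipanel <- ipanel + 1
    body <- c(body, sprintf('<g class="panel panel-structure">'),
              structurePanelSVG(fig, lay, ipanel), "</g>")
  }
  for (p in fig@panels) {
    ipanel <- ipanel + 1
    body <- c(body, sprintf('<g class="panel panel-%s">', p$metric),
              expressionPanelSVG(fig, lay, ipanel, p), "</g>")
  }
  # legend: one toggle-able entry per metadata group
  if (length(fig@legendGroups) > 0) {
    lx <- lay$width - 140
    ly <- lay$top + 10
    pal <- fig@config$palette
    for (i in seq_along(fig@legendGroups)) {
      g <- fig@legendGroups[i]
      y <- ly + (i - 1) * 24
      body <- c(body, sprintf(
        '<g class="legend-item" data-group="%s" cursor="pointer"><path d="M %s %s H %s V %s H %s Z" fill="%s"/><text x="%s" y="%s" font-size="13">%s</text></g>',
        svgEsc(g), fmt(lx), fmt(y), fmt(lx + 16), fmt(y + 16), fmt(lx), pal[[g]],
        fmt(lx + 22), fmt(y + 13), svgEsc(g)))
    }
  }
  c(head, body, "</svg>")
}

FIGURE_CSS <- c(
  "body { margin: 0; background: #ffffff; }",
  "#tooltip { position: fixed; display: none; background: rgba(30,30,30,0.92);",
  "  color: #ffffff; padding: 6px 9px; border-radius: 4px; font: 12px/1.4 sans-serif;",
  "  pointer-events: none; z-index: 10; max-width: 320px; }",
  ".legend-item.off { opacity: 0.3; }",
  ".hoverable:hover { opacity: 0.8; }",
  "text.tick, text.axis-label { font-size: 11px; fill: #555555; }",
  "text.panel-title { font-size: 14px; font-weight: bold; }"
)

# Interactive runtime: tooltip on hover, per-group legend toggling across
# all panels, wheel zoom + drag pan + double-click reset on the viewBox.
FIGURE_JS <- c(
  "(function () {",
  "  var svg = document.getElementById('figure');",
  "  var tip = document.getElementById('tooltip');",
  "  svg.querySelectorAll('[data-hover]').forEach(function (el) {",
  "    el.addEventListener('mousemove', function (ev) {",
  "      tip.innerHTML = el.getAttribute('data-hover');",
  "      tip.style.display = 'block';",
  "      tip.style.left = (ev.clientX + 14) + 'px';",
  "      tip.style.top = (ev.clientY + 14) + 'px';",
  "    });",
  "    el.addEventListener('mouseleave', function () { tip.style.display = 'none'; });",
  "  });",
  "  svg.querySelectorAll('.legend-item').forEach(function (item) {",
  "    item.addEventListener('click', function () {",
  "      var g = item.getAttribute('data-group');",
  "      var off = item.classList.toggle('off');",
  "      svg.querySelectorAll('[data-group]').forEach(function (el) {",
  "        if (el.getAttribute('data-group') === g && !el.classList.contains('legend-item')) {",
  "          el.style.display = off ? 'none' : '';",
  "        }",
  "      });",
  "    });",
  "  });",
  "  var vb0 = svg.getAttribute('viewBox').split(' ').map(Number);",
  "  var vb = vb0.slice();",
  "  function setVB() { svg.setAttribute('viewBox', vb.join(' ')); }",
  "  function svgPoint(ev) {",
  "    var pt = svg.createSVGPoint();",
  "    pt.x = ev.clientX; pt.y = ev.clientY;",
  "    return pt.matrixTransform(svg.getScreenCTM().inverse());",
  "  }",
  "  svg.addEventListener('wheel', function (ev) {",
  "    ev.preventDefault();",
  "    var p = svgPoint(ev);",
  "    var k = ev.deltaY < 0 ? 0.85 : 1 / 0.85;",
  "    vb[0] = p.x - (p.x - vb[0]) * k;",
  "    vb[1] = p.y - (p.y - vb[1]) * k;",
  "    vb[2] *= k; vb[3] *= k;",
  "    setVB();",
  "  }, { passive: false });",
  "  var drag = null;",
  "  svg.addEventListener('mousedown', function (ev) { drag = svgPoint(ev); });",
  "  window.addEventListener('mouseup', function () { drag = null; });",
  "  svg.addEventListener('mousemove', function (ev) {",
  "    if (!drag) return;",
  "    var p = svgPoint(ev);",
  "    vb[0] -= p.x - drag.x; vb[1] -= p.y - drag.y;",
  "    setVB();",
  "  });",
  "  svg.addEventListener('dblclick', function () { vb = vb0.slice(); setVB(); });",
  "})();"
)

#' Export a figure as interactive HTML
#'
#' Writes an HTML file rendering the figure as SVG with an embedded
#' JavaScript runtime providing hover tooltips, per-group legend toggling,
#' wheel zoom and drag pan.  With `selfContained = TRUE` (the default) the
#' runtime is inlined, so the file renders in a browser with no network
#' access; otherwise the runtime is written to a sidecar `.js` file next to
#' the HTML.  Output bytes are deterministic for identical figures (the
#' point jitter is seeded), so re-exports are reproducible.
#'
#' @param fig A [FigureSpec-class].
#' @param path Output HTML path.
#' @param selfContained Inline the runtime (default `TRUE`).
#' @param width,rowHeight Figure width and per-transcript row height in
#'   pixels.
#' @return Invisibly, the path written.
#' @export
exportHTML <- function(fig, path, selfContained = TRUE, width = 1200,
                       rowHeight = 70) {
  stopifnot(is(fig, "FigureSpec"))
  svg <- figureToSVG(fig, width, rowHeight)
  if (selfContained) {
    script <- c("<script>", FIGURE_JS, "</script>")
  } else {
    jspath <- paste0(tools::file_path_sans_ext(path), ".js")
    conj <- file(jspath, open = "wb")
    writeLines(FIGURE_JS, conj, sep = "\n")
    close(conj)
    script <- sprintf('<script src="%s"></script>', basename(jspath))
  }
  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", svgEsc(if (nzchar(fig@title)) fig@title else "Isoform figure")),
    "<style>", FIGURE_CSS, "</style>",
    "</head>",
    "<body>",
    svg,
    '<div id="tooltip"></div>',
    script,
    "</body>",
    "</html>"
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write HTML to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(html, con, sep = "\n")
  invisible(path)
}

# Base-graphics rendering used by the PNG/PDF static backends.
renderFigureBase <- function(fig, width = 1200, rowHeight = 70) {
  lay <- figureLayout(fig, width, rowHeight)
  n <- lay$n
  panels <- c(if (lay$has_struct) list(fig@structure) else list(), fig@panels)
  k <- length(panels)
  widths <- c(0.8, if (lay$has_struct) 2 else NULL, rep(1, length(fig@panels)))
  graphics::layout(matrix(seq_len(k + 1), nrow = 1), widths = widths)
  graphics::par(mar = c(4, 0, 3, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0.5, n + 0.5))
  for (i in seq_along(fig@rowOrder)) {
    graphics::text(0.95, n - i + 1, fig@rowOrder[i], adj = 1, cex = 0.9)
  }
  pal <- fig@config$palette
  for (p in panels) {
    xr <- padRange(p$xRange)
    graphics::par(mar = c(4, 1, 3, 1))
    graphics::plot.new()
    graphics::plot.window(xlim = xr, ylim = c(0.5, n + 0.5))
    graphics::axis(1, cex.axis = 0.8)
    graphics::title(main = p$title, cex.main = 0.95)
    if (p$kind == "structure") {
      sh <- p$shapes
      for (i in order(match(sh$kind, c("intron", "exon", "CDS")))) {
        r <- sh[i, ]
        if (r$kind == "intron") {
          graphics::segments(r$x0, r$y0, r$x1, r$y1, col = "#444444")
        } else {
          graphics::rect(r$x0, r$y0, r$x1, r$y1,
                         col = if (r$kind == "CDS") "#2c7fb8" else "#a6bddb",
                         border = "#1c3d5a")
        }
      }
      if (nrow(p$arrows) > 0) {
        pchdir <- ifelse(p$arrows$direction == "right", ">", "<")
        graphics::text(p$arrows$x, p$arrows$y, pchdir, cex = 0.6, col = "#444444")
      }
      graphics::mtext(sprintf("Display position (%s)", p$chrom), side = 1,
                      line = 2.5, cex = 0.7)
    } else {
      b <- p$boxes
      for (i in seq_len(nrow(b))) {
        r <- b[i, ]
        if (is.na(r$median)) next
        col <- pal[[r$group]]
        graphics::segments(r$whisker_low, r$y, r$lower_quartile, r$y, col = col)
        graphics::segments(r$upper_quartile, r$y, r$whisker_high, r$y, col = col)
        graphics::rect(r$lower_quartile, r$y - r$box_half,
                       r$upper_quartile, r$y + r$box_half,
                       col = grDevices::adjustcolor(col, alpha.f = 0.45), border = col)
        graphics::segments(r$median, r$y - r$box_half, r$median, r$y + r$box_half,
                           col = col, lwd = 2)
      }
      if (nrow(p$points) > 0) {
        graphics::points(p$points$value, p$points$y, pch = 21, cex = 0.7,
                         bg = pal[p$points$group], col = "white")
      }
    }
  }
  graphics::mtext(fig@title, side = 3, line = -1.5, outer = TRUE, cex = 1)
  invisible(NULL)
}

#' Export a figure as a static image
#'
#' Writes the same figure as [exportHTML()] to SVG, PNG or PDF.  SVG output
#' is produced by the package's own deterministic SVG writer (identical
#' figures give byte-identical files); PNG and PDF are rendered through the
#' corresponding `grDevices` device.
#'
#' @param fig A [FigureSpec-class].
#' @param path Output path.
#' @param format One of `"svg"`, `"png"`, `"pdf"` (case-insensitive;
#'   default: from the file extension).
#' @param width,rowHeight Figure width and per-transcript row height in
#'   pixels.
#' @return Invisibly, the path written.
#' @export
exportStatic <- function(fig, path, format = tools::file_ext(path),
                         width = 1200, rowHeight = 70) {
  stopifnot(is(fig, "FigureSpec"))
  format <- tolower(format)
  if (!format %in% c("svg", "png", "pdf")) {
    stop("unsupported static format '", format, "' (expected svg, png or pdf)",
         call. = FALSE)
  }
  if (format == "svg") {
    svg <- figureToSVG(fig, width, rowHeight, standalone = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(svg, con, sep = "\n")
    return(invisible(path))
  }
  lay <- figureLayout(fig, width, rowHeight)
  ok <- tryCatch({
    if (format == "png") {
      if (capabilities("cairo")) {
        grDevices::png(path, width = lay$width, height = ceiling(lay$height),
                       type = "cairo")
      } else {
        grDevices::png(path, width = lay$width, height = ceiling(lay$height))
      }
    } else {
      grDevices::pdf(path, width = lay$width / 96, height = lay$height / 96)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("static ", toupper(format),
         " backend unavailable on this system; use exportHTML() or SVG instead",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  renderFigureBase(fig, width, rowHeight)
  invisible(path)
}
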