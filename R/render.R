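# ---------------------------------------------------------------------------
# SVG rendering in the style of the cuticle panels: cell boundaries in red,
# tendon rows shaded grey, atypical cells magenta, clone cells yellow, one
# arrow per denticle encoding its orientation.
# ---------------------------------------------------------------------------

svg_num <- function(x) sprintf("%.3f", x)

#' Render a run (or a bare map) as an SVG drawing
#'
#' @param result A `run_result`, or a `cell_map` (cells only).
#' @param out Output path for the SVG file.
#' @return `out` invisibly.
#' @export
render_map <- function(result, out) {
  if (inherits(result, "cell_map")) {
    map <- result; denticles <- NULL; cells_cls <- NULL
  } else {
    map <- result$map; denticles <- result$denticles
    cells_cls <- result$cells
  }
  dir_ok <- dir.exists(dirname(out))
  if (!dir_ok) stop(sprintf("cannot write SVG: directory %s does not exist",
                            dirname(out)), call. = FALSE)
  xs <- unlist(lapply(map$polygons, function(p) p[, 1]))
  ys <- unlist(lapply(map$polygons, function(p) p[, 2]))
  pad <- 5
  vb <- c(min(xs) - pad, min(ys) - pad,
          diff(range(xs)) + 2 * pad, diff(range(ys)) + 2 * pad)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" viewBox=',
                   '"%s %s %s %s" width="%s" height="%s">'),
            svg_num(vb[1]), svg_num(vb[2]), svg_num(vb[3]), svg_num(vb[4]),
            svg_num(vb[3] * 2), svg_num(vb[4] * 2)),
    '<g class="cells" stroke="#c0392b" stroke-width="0.6">'
  )
  for (i in seq_len(nrow(map$cells))) {
    r <- map$cells[i, ]
    poly <- map$polygons[[as.character(r$id)]]
    fill <- if (r$is_tendon) "#d5d5d5"
      else if (r$ectods_clone) "#f7e26b"
      else if (r$is_atypical) "#f2b6de"
      else if (r$is_gap_filler) "#cfe8f5"
      else "#fdf8f0"
    pts <- paste(apply(poly, 1, function(v)
      paste0(svg_num(v[1]), ",", svg_num(v[2]))), collapse = " ")
    extra <- if (r$ectods_clone) ' stroke="#b8860b" stroke-width="1.2"' else ""
    lines <- c(lines, sprintf(
      '<polygon class="cell row-%s" points="%s" fill="%s"%s/>',
      r$row_label, pts, fill, extra))
  }
  lines <- c(lines, "</g>")

  if (!is.null(denticles) && nrow(denticles) > 0) {
    lines <- c(lines, '<g class="denticles" stroke="#1b5e20" stroke-width="0.8" fill="#1b5e20">')
    half <- 3
    for (i in seq_len(nrow(denticles))) {
      d <- denticles[i, ]
      dir <- if (d$orientation == "anterior") -1 else 1
      x0 <- d$x - dir * half; x1 <- d$x + dir * half
      tipx <- x1 + dir * 1.5
      lines <- c(lines, sprintf(
        paste0('<g class="denticle %s"><line x1="%s" y1="%s" x2="%s" y2="%s"/>',
               '<polygon points="%s,%s %s,%s %s,%s"/></g>'),
        d$orientation,
        svg_num(x0), svg_num(d$y), svg_num(x1), svg_num(d$y),
        svg_num(tipx), svg_num(d$y),
        svg_num(x1), svg_num(d$y - 1.2), svg_num(x1), svg_num(d$y + 1.2)))
    }
    lines <- c(lines, "</g>")
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out)
  invisible(out)
}
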