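#' Export the laid-out difference graph as SVG
#'
#' Emits, in paint order: compartment boxes, arcs (bends rendered as
#' elliptical-arc path segments, arrow-head markers referenced from shared
#' definitions), then node glyphs with labels. Stroke colours follow the
#' change-class colour scheme. Byte-deterministic for identical inputs.
#'
#' @param g a `diff_graph`
#' @param geo a `geometry` from [run_layout()]
#' @param scheme a [colour_scheme()]
#' @param p layout parameters (canvas size)
#' @return single character string holding the SVG document
#' @export
write_svg <- function(g, geo, scheme = colour_scheme(), p = layout_params()) {
  stopifnot(inherits(g, "diff_graph"), inherits(geo, "geometry"))
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  lib <- glyph_path_library()
  non_comp <- g$nodes$id[g$nodes$kind != "compartment"]
  missing <- setdiff(non_comp, geo$positions$id)
  if (length(missing)) {
    stop_sbgndiff("sbgndiff_export_error",
                  "no geometry for node '%s'", missing[1L])
  }
  pos <- function(id) {
    i <- match(id, geo$positions$id)
    c(geo$positions$x[i], geo$positions$y[i])
  }
  size_of <- function(id) {
    i <- match(id, geo$sizes$id)
    c(geo$sizes$w[i], geo$sizes$h[i])
  }

  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" ',
           'viewBox="0 0 %s %s">'),
    fmt(p$canvas_width), fmt(p$canvas_height),
    fmt(p$canvas_width), fmt(p$canvas_height)))

  # marker definitions: one per (head class, colour) combination in use
  headed <- g$links$arc_class %in% names(lib$markers)
  combos <- unique(data.frame(
    arc = g$links$arc_class[headed],
    col = vapply(g$links$change[headed], function(ch) {
      scheme_colour(scheme, ch)
    }, ""), stringsAsFactors = FALSE))
  marker_id <- function(arc, col) paste0("head-", arc, "-", sub("^#", "", col))
  if (nrow(combos)) {
    out <- c(out, "  <defs>")
    for (i in seq_len(nrow(combos))) {
      mk <- lib$markers[[combos$arc[i]]]
      fill <- if (identical(mk$fill, "stroke")) combos$col[i] else mk$fill
      out <- c(out, sprintf(
        paste0('    <marker id="%s" viewBox="0 0 10 10" refX="9" refY="5" ',
               'markerWidth="8" markerHeight="8" orient="auto-start-reverse">',
               '<path d="%s" fill="%s" stroke="%s" stroke-width="1"/></marker>'),
        marker_id(combos$arc[i], combos$col[i]), mk$d, fill, combos$col[i]))
    }
    out <- c(out, "  </defs>")
  }

  out <- c(out, '  <g class="drawing">')

  # compartment boxes (painted beneath everything; parents first)
  label_of <- stats::setNames(g$nodes$label, g$nodes$id)
  change_of <- stats::setNames(g$nodes$change, g$nodes$id)
  if (NROW(geo$boxes)) {
    for (i in seq_len(nrow(geo$boxes))) {
      b <- geo$boxes[i, ]
      col <- scheme_colour(scheme, change_of[[b$compartment_id]])
      out <- c(out, sprintf(
        paste0('    <rect class="compartment" id="%s" x="%s" y="%s" ',
               'width="%s" height="%s" rx="10" fill="none" stroke="%s" ',
               'stroke-width="2"/>'),
        xml_escape(b$compartment_id), fmt(b$x0), fmt(b$y0),
        fmt(b$x1 - b$x0), fmt(b$y1 - b$y0), col))
      out <- c(out, sprintf(
        '    <text class="compartment-label" x="%s" y="%s" font-size="12">%s</text>',
        fmt(b$x0 + 4), fmt(b$y0 + 14),
        xml_escape(label_of[[b$compartment_id]])))
    }
  }

  # arcs
  for (k in seq_len(NROW(g$links))) {
    l <- g$links[k, ]
    P0 <- pos(l$source); P1 <- pos(l$target)
    col <- scheme_colour(scheme, l$change)
    rank <- geo$bends$rank[match(k, geo$bends$link)]
    sag <- geo$bends$sagitta[match(k, geo$bends$link)]
    ah <- if (NROW(geo$arrowheads)) {
      geo$arrowheads[geo$arrowheads$link == k, , drop = FALSE]
    } else geo$arrowheads
    Pend <- if (NROW(ah)) c(ah$x[1], ah$y[1]) else P1
    d_attr <- if (!is.na(rank) && rank != 0L && sag > 0) {
      clen <- sqrt(sum((Pend - P0)^2))
      R <- (clen^2 / 4 + sag^2) / (2 * sag)
      sweep <- if (rank > 0) 1 else 0
      sprintf("M %s %s A %s %s 0 0 %d %s %s", fmt(P0[1]), fmt(P0[2]),
              fmt(R), fmt(R), sweep, fmt(Pend[1]), fmt(Pend[2]))
    } else {
      sprintf("M %s %s L %s %s", fmt(P0[1]), fmt(P0[2]),
              fmt(Pend[1]), fmt(Pend[2]))
    }
    marker_attr <- if (NROW(ah)) {
      sprintf(' marker-end="url(#%s)"', marker_id(l$arc_class, col))
    } else ""
    out <- c(out, sprintf(
      '    <path class="arc %s" d="%s" fill="none" stroke="%s" stroke-width="2"%s/>',
      l$arc_class, d_attr, col, marker_attr))
  }

  # node glyphs with labels
  for (i in which(g$nodes$kind != "compartment")) {
    nd <- g$nodes[i, ]
    c_ <- pos(nd$id); s_ <- size_of(nd$id)
    col <- scheme_colour(scheme, nd$change)
    path_d <- lib$glyphs[[nd$glyph]](c_, s_)
    out <- c(out, sprintf('    <g class="glyph %s" id="%s">', nd$glyph,
                          xml_escape(nd$id)))
    out <- c(out, sprintf(
      '      <path d="%s" fill="#ffffff" stroke="%s" stroke-width="2"/>',
      path_d, col))
    if (nzchar(nd$label) && nd$kind == "entity") {
      out <- c(out, sprintf(
        paste0('      <text x="%s" y="%s" text-anchor="middle" ',
               'font-size="11">%s</text>'),
        fmt(c_[1]), fmt(c_[2] + s_[2] / 2 + 12), xml_escape(nd$label)))
    }
    out <- c(out, "    </g>")
  }

  out <- c(out, "  </g>", "</svg>", "")
  paste(out, collapse = "\n")
}
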