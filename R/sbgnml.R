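#' Export the laid-out difference graph as SBGN-ML
#'
#' Writes an SBGN-ML 0.2 process-description map: one glyph per node with
#' its class, bounding box and label, compartments with their computed
#' boxes, and one arc per link with start/end coordinates (the arrow-head
#' anchor as end point for head-bearing arcs). Difference highlighting is
#' carried twice: a render-extension block defines one style per change
#' class and assigns element ids to styles, and every changed element
#' carries an annotation referencing the matching COMODI concept
#' (insertion / deletion / update). Ports are omitted.
#'
#' @param g a `diff_graph`
#' @param geo a `geometry` from [run_layout()]
#' @param scheme a [colour_scheme()]
#' @return single character string holding the SBGN-ML document
#' @export
write_sbgnml <- function(g, geo, scheme = colour_scheme()) {
  stopifnot(inherits(g, "diff_graph"), inherits(geo, "geometry"))
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  non_comp <- g$nodes$id[g$nodes$kind != "compartment"]
  missing <- setdiff(non_comp, geo$positions$id)
  if (length(missing)) {
    stop_sbgndiff("sbgndiff_export_error",
                  "no geometry for node '%s'", missing[1L])
  }
  sbgn_class <- function(glyph) {
    switch(glyph,
           `unspecified-entity` = "unspecified entity",
           `simple-chemical` = "simple chemical",
           `nucleic-acid-feature` = "nucleic acid feature",
           `empty-set` = "source and sink",
           glyph)   # macromolecule, complex, process, compartment
  }
  arc_class_sbgn <- function(arc) {
    if (arc == "necessary-stimulation") "necessary stimulation" else arc
  }
  comodi_iri <- function(change) {
    base <- "http://purl.uni-rostock.de/comodi/comodi#"
    switch(change, insert = paste0(base, "Insertion"),
           delete = paste0(base, "Deletion"),
           update = paste0(base, "Update"), NULL)
  }
  annotation_xml <- function(elem_id, change, indent) {
    iri <- comodi_iri(change)
    if (is.null(iri)) return(character())
    pad <- strrep(" ", indent)
    c(sprintf("%s<annotation>", pad),
      sprintf(paste0(
        '%s  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
        'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">'), pad),
      sprintf('%s    <rdf:Description rdf:about="#%s">', pad,
              xml_escape(elem_id)),
      sprintf('%s      <bqbiol:is rdf:resource="%s"/>', pad, iri),
      sprintf("%s    </rdf:Description>", pad),
      sprintf("%s  </rdf:RDF>", pad),
      sprintf("%s</annotation>", pad))
  }

  pos <- function(id) {
    i <- match(id, geo$positions$id)
    c(geo$positions$x[i], geo$positions$y[i])
  }
  size_of <- function(id) {
    i <- match(id, geo$sizes$id)
    c(geo$sizes$w[i], geo$sizes$h[i])
  }
  arc_id <- function(k) sprintf("arc%d", k)

  # render extension: one style per non-black change class actually in use
  styled <- list(insert = character(), delete = character(),
                 update = character())
  for (i in seq_len(nrow(g$nodes))) {
    ch <- g$nodes$change[i]
    if (ch %in% names(styled)) styled[[ch]] <- c(styled[[ch]], g$nodes$id[i])
  }
  for (k in seq_len(NROW(g$links))) {
    ch <- g$links$change[k]
    if (ch %in% names(styled)) styled[[ch]] <- c(styled[[ch]], arc_id(k))
  }

  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">',
           '  <map language="process description" id="map1">')
  used <- names(styled)[vapply(styled, length, 0L) > 0L]
  if (length(used)) {
    out <- c(out, "    <extension>",
             paste0('      <renderInformation id="diffRender" ',
                    'xmlns="http://www.sbml.org/sbml/level3/version1/render/version1" ',
                    'programName="sbgndiff">'),
             "        <listOfColorDefinitions>")
    for (cls in used) {
      out <- c(out, sprintf(
        '          <colorDefinition id="colour_%s" value="%s"/>',
        cls, scheme_colour(scheme, cls)))
    }
    out <- c(out, "        </listOfColorDefinitions>",
             "        <listOfStyles>")
    for (cls in used) {
      out <- c(out, sprintf(
        '          <style id="style_%s" idList="%s"><g stroke="colour_%s" stroke-width="2"/></style>',
        cls, paste(styled[[cls]], collapse = " "), cls))
    }
    out <- c(out, "        </listOfStyles>", "      </renderInformation>",
             "    </extension>")
  }

  # compartment glyphs first (containers), then entity/process glyphs
  for (i in which(g$nodes$kind == "compartment")) {
    nd <- g$nodes[i, ]
    b <- geo$boxes[geo$boxes$compartment_id == nd$id, , drop = FALSE]
    if (!nrow(b)) {
      stop_sbgndiff("sbgndiff_export_error",
                    "no geometry for compartment '%s'", nd$id)
    }
    out <- c(out, sprintf('    <glyph id="%s" class="compartment"%s>',
                          xml_escape(nd$id),
                          if (!is.na(nd$compartment)) {
                            sprintf(' compartmentRef="%s"',
                                    xml_escape(nd$compartment))
                          } else ""))
    out <- c(out, annotation_xml(nd$id, nd$change, 6L))
    out <- c(out, sprintf('      <label text="%s"/>', xml_escape(nd$label)),
             sprintf('      <bbox x="%s" y="%s" w="%s" h="%s"/>',
                     fmt(b$x0[1]), fmt(b$y0[1]), fmt(b$x1[1] - b$x0[1]),
                     fmt(b$y1[1] - b$y0[1])),
             "    </glyph>")
  }
  for (i in which(g$nodes$kind != "compartment")) {
    nd <- g$nodes[i, ]
    c_ <- pos(nd$id); s_ <- size_of(nd$id)
    out <- c(out, sprintf('    <glyph id="%s" class="%s"%s>',
                          xml_escape(nd$id), sbgn_class(nd$glyph),
                          if (!is.na(nd$compartment)) {
                            sprintf(' compartmentRef="%s"',
                                    xml_escape(nd$compartment))
                          } else ""))
    out <- c(out, annotation_xml(nd$id, nd$change, 6L))
    out <- c(out, sprintf('      <label text="%s"/>', xml_escape(nd$label)),
             sprintf('      <bbox x="%s" y="%s" w="%s" h="%s"/>',
                     fmt(c_[1] - s_[1] / 2), fmt(c_[2] - s_[2] / 2),
                     fmt(s_[1]), fmt(s_[2])),
             "    </glyph>")
  }
  for (k in seq_len(NROW(g$links))) {
    l <- g$links[k, ]
    P0 <- pos(l$source); P1 <- pos(l$target)
    ah <- if (NROW(geo$arrowheads)) {
      geo$arrowheads[geo$arrowheads$link == k, , drop = FALSE]
    } else geo$arrowheads
    Pend <- if (NROW(ah)) c(ah$x[1], ah$y[1]) else P1
    out <- c(out, sprintf(
      '    <arc id="%s" class="%s" source="%s" target="%s">',
      arc_id(k), arc_class_sbgn(l$arc_class), xml_escape(l$source),
      xml_escape(l$target)))
    out <- c(out, annotation_xml(arc_id(k), l$change, 6L))
    out <- c(out, sprintf('      <start x="%s" y="%s"/>', fmt(P0[1]), fmt(P0[2])),
             sprintf('      <end x="%s" y="%s"/>', fmt(Pend[1]), fmt(Pend[2])),
             "    </arc>")
  }
  out <- c(out, "  </map>", "</sbgn>", "")
  paste(out, collapse = "\n")
}

#' Rasterise an SVG export to PNG
#'
#' Optional capability: requires an external SVG rasteriser (the `rsvg` R
#' package or an `rsvg-convert` / ImageMagick `convert` binary on the PATH).
#' When none is available this degrades to a clear capability error rather
#' than a crash.
#'
#' @param svg SVG document text
#' @param path output PNG path
#' @param scale scale factor applied to the canvas size
#' @return `path`, invisibly
#' @export
write_png <- function(svg, path, scale = 1) {
  wh <- regmatches(svg, regexec('width="([0-9.]+)" height="([0-9.]+)"', svg))[[1]]
  if (length(wh) == 3L) {
    w <- round(as.numeric(wh[2]) * scale)
    h <- round(as.numeric(wh[3]) * scale)
  } else {
    w <- h <- NA_integer_
  }
  tmp <- tempfile(fileext = ".svg")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(svg, tmp)
  if (requireNamespace("rsvg", quietly = TRUE)) {
    rsvg::rsvg_png(tmp, path, width = w, height = h)
    return(invisible(path))
  }
  for (tool in c("rsvg-convert", "convert")) {
    if (nzchar(Sys.which(tool))) {
      args <- if (tool == "rsvg-convert") {
        c("-o", path, if (!is.na(w)) c("-w", w, "-h", h), tmp)
      } else {
        c(tmp, path)
      }
      status <- suppressWarnings(system2(tool, args, stdout = FALSE,
                                         stderr = FALSE))
      if (identical(status, 0L) && file.exists(path)) return(invisible(path))
    }
  }
  stop_sbgndiff("sbgndiff_capability_error",
                "PNG export requires an SVG rasteriser (rsvg package, rsvg-convert or ImageMagick convert); none is available")
}
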