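#' JSON interchange format for difference graphs
#'
#' The interchange document has two top-level arrays, `nodes` and `links`.
#' Node attributes: `id` (required), `label`, `compartment`, `sboTerm`,
#' `bivesChange`. Link attributes: `source`, `target` (required), `class`,
#' `bivesClass`. Optional attributes are omitted when they hold their
#' defaults (`bivesChange`/`bivesClass` absent means unchanged; an absent
#' `sboTerm` means the default glyph, the unspecified entity). A JSON-Schema
#' document describing the format ships at
#' `system.file("schema", "diff-graph.schema.json", package = "sbgndiff")`.
#'
#' @name graph_json
NULL

#' Serialise a difference graph to interchange JSON
#'
#' @param g a `diff_graph`
#' @param pretty pretty-print the JSON
#' @return single JSON string
#' @export
to_json <- function(g, pretty = TRUE) {
  stopifnot(inherits(g, "diff_graph"))
  validate_diff_graph(g)
  node_obj <- function(i) {
    n <- g$nodes[i, ]
    o <- list(id = n$id)
    if (!is.na(n$label) && nzchar(n$label)) o$label <- n$label
    if (!is.na(n$compartment)) o$compartment <- n$compartment
    if (!is.na(n$sbo)) o$sboTerm <- n$sbo
    if (n$change != "none") o$bivesChange <- n$change
    if (n$kind == "compartment") o$isCompartment <- TRUE
    o
  }
  link_obj <- function(i) {
    l <- g$links[i, ]
    o <- list(source = l$source, target = l$target, class = l$arc_class)
    if (l$change != "none") o$bivesClass <- l$change
    o
  }
  doc <- list(nodes = lapply(seq_len(nrow(g$nodes)), node_obj),
              links = lapply(seq_len(nrow(g$links)), link_obj))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty,
                                null = "null"))
}

#' Parse interchange JSON back into a difference graph
#'
#' Enforces the packaged schema's rules in code: `nodes`/`links` arrays,
#' required `id`/`source`/`target`, closed vocabularies, and endpoint
#' resolution. Missing optional attributes take their defaults (glyph
#' `unspecified-entity` via the absent SBO term, change `none`).
#'
#' @param text JSON string or path to a JSON file
#' @return a validated `diff_graph`
#' @export
from_json <- function(text) {
  if (length(text) == 1L && !grepl("{", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) {
                    stop_sbgndiff("sbgndiff_validation_error",
                                  "invalid JSON: %s", conditionMessage(e))
                  })
  if (!is.list(doc) || !all(c("nodes", "links") %in% names(doc))) {
    stop_sbgndiff("sbgndiff_validation_error",
                  "document must contain 'nodes' and 'links' arrays")
  }
  get_chr <- function(o, key, default = NA_character_) {
    v <- o[[key]]
    if (is.null(v)) default else as.character(v)
  }
  nodes <- lapply(doc$nodes, function(o) {
    if (is.null(o$id)) {
      stop_sbgndiff("sbgndiff_validation_error", "node without an 'id'")
    }
    sbo <- get_chr(o, "sboTerm")
    change <- get_chr(o, "bivesChange", "none")
    if (!(change %in% c("insert", "delete", "update", "move", "none"))) {
      stop_sbgndiff("sbgndiff_validation_error",
                    "node '%s' has unknown bivesChange '%s'", o$id, change)
    }
    glyph <- if (isTRUE(o$isCompartment)) "compartment" else sbo_to_glyph(sbo)
    kind <- switch(glyph, process = "process",
                   `empty-set` = "source_sink",
                   compartment = "compartment", "entity")
    data.frame(id = as.character(o$id), label = get_chr(o, "label", ""),
               compartment = get_chr(o, "compartment"), sbo = sbo,
               glyph = glyph, change = change, kind = kind,
               stringsAsFactors = FALSE)
  })
  links <- lapply(doc$links, function(o) {
    if (is.null(o$source) || is.null(o$target)) {
      stop_sbgndiff("sbgndiff_validation_error",
                    "link without 'source' and 'target'")
    }
    arc <- get_chr(o, "class", "consumption")
    if (!(arc %in% ARC_CLASSES)) {
      stop_sbgndiff("sbgndiff_validation_error",
                    "link %s->%s has unknown class '%s'",
                    o$source, o$target, arc)
    }
    data.frame(source = as.character(o$source),
               target = as.character(o$target), arc_class = arc,
               change = get_chr(o, "bivesClass", "none"),
               stringsAsFactors = FALSE)
  })
  nodes <- if (length(nodes)) do.call(rbind, nodes) else empty_nodes()
  links <- if (length(links)) do.call(rbind, links) else empty_links()
  rownames(nodes) <- rownames(links) <- NULL
  nodes$label[is.na(nodes$label)] <- ""
  bad <- setdiff(c(links$source, links$target), nodes$id)
  if (length(bad)) {
    stop_sbgndiff("sbgndiff_validation_error",
                  "link refers to unknown node '%s'", bad[1L])
  }
  tryCatch(new_diff_graph(nodes, links), error = function(e) {
    stop_sbgndiff("sbgndiff_validation_error", "%s", conditionMessage(e))
  })
}
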