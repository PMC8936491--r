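#' Unified SBGN PD difference graph
#'
#' The difference graph is the union of both model versions, translated to
#' SBGN Process Description structure: one entity node per species, one
#' process node per reaction (so that every participant arc starts or ends at
#' a process node, keeping the graph bipartite), source/sink nodes standing
#' in for absent reactants/products, and compartment nodes for grouping.
#' Every node and link carries exactly one change class from the diff.
#'
#' @name diff_graph
NULL

SOURCE_SUFFIX <- "__source"
SINK_SUFFIX <- "__sink"

new_diff_graph <- function(nodes, links) {
  g <- structure(list(nodes = nodes, links = links), class = "diff_graph")
  validate_diff_graph(g)
}

empty_nodes <- function() {
  data.frame(id = character(), label = character(), compartment = character(),
             sbo = character(), glyph = character(), change = character(),
             kind = character(), stringsAsFactors = FALSE)
}

empty_links <- function() {
  data.frame(source = character(), target = character(),
             arc_class = character(), change = character(),
             stringsAsFactors = FALSE)
}

#' Validate difference-graph invariants
#'
#' Checks id uniqueness, endpoint resolution, bipartiteness (exactly one
#' endpoint of every link is a process node), arc orientation (consumption
#' into / production out of a process), compartment-reference resolution, and
#' change-class totality.
#'
#' @param g a `diff_graph`
#' @return `g` (errors on violation)
#' @export
validate_diff_graph <- function(g) {
  n <- g$nodes; l <- g$links
  if (anyDuplicated(n$id)) {
    stop_sbgndiff("sbgndiff_integrity_error", "duplicate node id: %s",
                  n$id[duplicated(n$id)][1L])
  }
  stopifnot(all(n$glyph %in% GLYPH_CLASSES),
            all(n$kind %in% c("entity", "process", "source_sink", "compartment")),
            all(n$change %in% c("insert", "delete", "update", "move", "none")),
            all(l$change %in% c("insert", "delete", "update", "move", "none")),
            all(l$arc_class %in% ARC_CLASSES))
  if (any(n$kind == "process" & n$glyph != "process") ||
      any(n$kind == "source_sink" & n$glyph != "empty-set")) {
    stop_sbgndiff("sbgndiff_integrity_error",
                  "node kind / glyph mismatch (process or source/sink)")
  }
  bad <- setdiff(c(l$source, l$target), n$id)
  if (length(bad)) {
    stop_sbgndiff("sbgndiff_integrity_error",
                  "link endpoint does not resolve to a node: %s", bad[1L])
  }
  comp_ids <- n$id[n$kind == "compartment"]
  badc <- setdiff(stats::na.omit(n$compartment), comp_ids)
  if (length(badc)) {
    stop_sbgndiff("sbgndiff_integrity_error",
                  "compartment reference does not resolve: %s", badc[1L])
  }
  if (nrow(l)) {
    is_proc <- stats::setNames(n$kind == "process", n$id)
    src_p <- is_proc[l$source]; tgt_p <- is_proc[l$target]
    if (any(src_p == tgt_p)) {
      stop_sbgndiff("sbgndiff_integrity_error",
                    "link violates bipartiteness (both or neither endpoint a process)")
    }
    if (any(l$arc_class == "consumption" & !tgt_p) ||
        any(l$arc_class == "production" & !src_p)) {
      stop_sbgndiff("sbgndiff_integrity_error",
                    "consumption must enter / production must leave a process node")
    }
  }
  g
}

#' @export
print.diff_graph <- function(x, ...) {
  cat(sprintf("<diff_graph: %d nodes (%d entities, %d processes, %d compartments), %d links>\n",
              nrow(x$nodes), sum(x$nodes$kind == "entity"),
              sum(x$nodes$kind == "process"),
              sum(x$nodes$kind == "compartment"), nrow(x$links)))
  invisible(x)
}

#' Build the unified SBGN PD difference graph of two model versions
#'
#' Translates species to entity nodes, reactions to process nodes with
#' consumption/production/modulation arcs, adds source/sink nodes for
#' reactions whose reactant or product lists are empty in both versions, and
#' compartment nodes for every compartment of either version. Each element
#' carries the change class from `cs`; a participant role change materialises
#' as one deleted link plus one inserted link.
#'
#' @param a,b `sbml_model` objects
#' @param cs the `change_set` from [classify()] for the same pair
#' @return a validated `diff_graph`
#' @examples
#' m <- read_sbml(generate_base_model(4, 2, 1, sbo_coverage = 1, seed = 7))
#' g <- build_network(m, m, classify(m, m))
#' g
#' @export
build_network <- function(a, b, cs) {
  stopifnot(inherits(a, "sbml_model"), inherits(b, "sbml_model"),
            inherits(cs, "change_set"))
  # map version-A ids to the unified (version-B preferred) ids
  ab_id <- stats::setNames(cs$mapping$matched$id_b,
                           paste0(cs$mapping$matched$kind, ":",
                                  cs$mapping$matched$id_a))
  unify <- function(kind, id_a) {
    key <- paste0(kind, ":", id_a)
    if (key %in% names(ab_id)) ab_id[[key]] else id_a
  }
  class_for <- function(kind, id) {
    key <- entity_key(kind, id)
    if (!(key %in% names(cs$class_of))) {
      stop_sbgndiff("sbgndiff_integrity_error",
                    "change set does not cover entity %s", key)
    }
    cs$class_of[[key]]
  }

  nodes <- list(); links <- list()
  add_node <- function(id, label, compartment, sbo, glyph, change, kind) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, label = label, compartment = compartment, sbo = sbo,
      glyph = glyph, change = change, kind = kind, stringsAsFactors = FALSE)
  }
  add_link <- function(source, target, arc_class, change) {
    links[[length(links) + 1L]] <<- data.frame(
      source = source, target = target, arc_class = arc_class,
      change = change, stringsAsFactors = FALSE)
  }

  # union over entities: matched + only-in-B are taken from B, deletions from A
  union_entities <- function(kind) {
    out <- list()
    for (e in entity_pool(b, kind)) out[[e$id]] <- list(e = e, from = "b")
    for (i in seq_len(nrow(cs$mapping$only_in_a))) {
      if (cs$mapping$only_in_a$kind[i] == kind) {
        id <- cs$mapping$only_in_a$id[i]
        out[[id]] <- list(e = model_entity(a, kind, id), from = "a")
      }
    }
    out
  }

  for (ce in union_entities("compartment")) {
    e <- ce$e
    parent <- if (is.na(e$parent)) NA_character_ else
      unify("compartment", e$parent)
    add_node(e$id, e$name %||% e$id, parent, NA_character_, "compartment",
             class_for("compartment", e$id), "compartment")
  }
  for (se in union_entities("species")) {
    e <- se$e
    comp <- if (is.na(e$compartment)) NA_character_ else
      if (se$from == "a") unify("compartment", e$compartment) else e$compartment
    add_node(e$id, e$name %||% e$id, comp, e$sbo_term,
             sbo_to_glyph(e$sbo_term), class_for("species", e$id), "entity")
  }

  rx_union <- union_entities("reaction")
  entity_node_ids <- vapply(nodes, function(n) n$id, "")
  for (re in rx_union) {
    r <- re$e
    rid <- r$id
    r_change <- class_for("reaction", rid)
    comp <- if (is.na(r$compartment)) NA_character_ else
      if (re$from == "a") unify("compartment", r$compartment) else r$compartment
    add_node(rid, r$name %||% rid, comp, "SBO:0000375", "process",
             r_change, "process")

    # participant (species, role, sbo) views of both versions, on unified ids
    part_view <- function(model, version_tag) {
      rr <- model_entity(model, "reaction",
                         if (version_tag == "a") {
                           # the A-side id of this reaction, if mapped
                           mt <- cs$mapping$matched
                           hit <- mt$id_a[mt$kind == "reaction" & mt$id_b == rid]
                           if (length(hit)) hit else rid
                         } else rid)
      if (is.null(rr)) return(NULL)
      ps <- c(rr$reactants, rr$products, rr$modifiers)
      if (!length(ps)) {
        return(data.frame(species = character(), role = character(),
                          sbo = character(), stringsAsFactors = FALSE))
      }
      data.frame(
        species = vapply(ps, function(p) {
          if (version_tag == "a") unify("species", p$species) else p$species
        }, ""),
        role = vapply(ps, `[[`, "", "role"),
        sbo = vapply(ps, function(p) p$sbo_term %||% NA_character_, ""),
        stringsAsFactors = FALSE)
    }
    pa <- part_view(a, "a"); pb <- part_view(b, "b")
    in_a <- !is.null(pa); in_b <- !is.null(pb)
    keyify <- function(d) if (is.null(d)) character() else paste(d$species, d$role)
    ka <- keyify(pa); kb <- keyify(pb)
    all_keys <- union(kb, ka)                      # B order first
    for (k in all_keys) {
      ia <- match(k, ka); ib <- match(k, kb)
      row <- if (!is.na(ib)) pb[ib, ] else pa[ia, ]
      link_change <-
        if (!in_a) "insert"                  # reaction only in B
        else if (!in_b) "delete"             # reaction only in A
        else if (is.na(ia)) "insert"
        else if (is.na(ib)) "delete"
        else "none"
      arc <- sbo_to_arc(row$role, row$sbo)
      if (row$role == "product") add_link(rid, row$species, arc, link_change)
      else add_link(row$species, rid, arc, link_change)
    }

    # source / sink stand-ins when a role list is empty in both versions
    roles_present <- function(d, role) !is.null(d) && any(d$role == role)
    no_reactants <- !roles_present(pa, "reactant") && !roles_present(pb, "reactant")
    no_products <- !roles_present(pa, "product") && !roles_present(pb, "product")
    if (no_reactants) {
      sid <- paste0(rid, SOURCE_SUFFIX)
      if (sid %in% entity_node_ids) {
        stop_sbgndiff("sbgndiff_integrity_error",
                      "synthesised source id collides: %s", sid)
      }
      add_node(sid, "", comp, "SBO:0000291", "empty-set", r_change, "source_sink")
      add_link(sid, rid, "consumption", r_change)
    }
    if (no_products) {
      sid <- paste0(rid, SINK_SUFFIX)
      if (sid %in% entity_node_ids) {
        stop_sbgndiff("sbgndiff_integrity_error",
                      "synthesised sink id collides: %s", sid)
      }
      add_node(sid, "", comp, "SBO:0000291", "empty-set", r_change, "source_sink")
      add_link(rid, sid, "production", r_change)
    }
  }

  nodes <- if (length(nodes)) do.call(rbind, nodes) else empty_nodes()
  links <- if (length(links)) do.call(rbind, links) else empty_links()
  rownames(nodes) <- rownames(links) <- NULL
  new_diff_graph(nodes, links)
}
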