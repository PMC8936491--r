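#' Semantics-aware diff of two condensed SBML models
#'
#' Entities of the two versions are first mapped onto each other (by id, then
#' by unique name within kind), then every element is classified into one of
#' four change classes:
#'
#' * `insert` — present only in the second version,
#' * `delete` — present only in the first version,
#' * `update` — mapped, with at least one attribute / participant /
#'   kinetic-law / annotation change,
#' * `none`   — mapped and unchanged (pure document moves keep this class;
#'   they affect change reports, not the network).
#'
#' Because the comparison works on the parsed model, whitespace and attribute
#' reorder never produce changes — unlike a line-based diff, which reports
#' spurious deletions and insertions for them.
#'
#' @name diff_engine
NULL

entity_kinds <- c("compartment", "species", "reaction")

entity_pool <- function(m, kind) {
  switch(kind, compartment = m$compartments, species = m$species,
         reaction = m$reactions)
}

#' Map entities between two model versions
#'
#' Same-kind entities sharing an id are matched; remaining unmatched entities
#' are matched by equal, side-unique name; the rest are reported as present in
#' only one version.
#'
#' @param a,b `sbml_model` objects (old and new version)
#' @return list with data.frames `matched` (`id_a`, `id_b`, `kind`),
#'   `only_in_a`, `only_in_b` (`id`, `kind`)
#' @export
map_entities <- function(a, b) {
  matched <- list(); only_a <- list(); only_b <- list()
  for (kind in entity_kinds) {
    pa <- entity_pool(a, kind); pb <- entity_pool(b, kind)
    ids_a <- entity_ids(pa); ids_b <- entity_ids(pb)
    common <- intersect(ids_a, ids_b)
    rest_a <- setdiff(ids_a, common); rest_b <- setdiff(ids_b, common)
    if (length(common)) {
      matched[[length(matched) + 1L]] <-
        data.frame(id_a = common, id_b = common, kind = kind,
                   stringsAsFactors = FALSE)
    }
    # fallback: unique-name match among the leftovers
    if (length(rest_a) && length(rest_b)) {
      name_of <- function(pool, ids) {
        nm <- vapply(pool, function(e) e$name %||% NA_character_, "")
        stats::setNames(nm[match(ids, entity_ids(pool))], ids)
      }
      na_ <- name_of(pa, rest_a); nb_ <- name_of(pb, rest_b)
      for (id_a in rest_a) {
        nm <- na_[[id_a]]
        if (is.na(nm)) next
        if (sum(na_ == nm, na.rm = TRUE) != 1L) next
        hit <- names(nb_)[which(!is.na(nb_) & nb_ == nm)]
        if (length(hit) == 1L && hit %in% rest_b) {
          matched[[length(matched) + 1L]] <-
            data.frame(id_a = id_a, id_b = hit, kind = kind,
                       stringsAsFactors = FALSE)
          rest_b <- setdiff(rest_b, hit)
          rest_a <- setdiff(rest_a, id_a)
        }
      }
    }
    if (length(rest_a)) {
      only_a[[length(only_a) + 1L]] <-
        data.frame(id = rest_a, kind = kind, stringsAsFactors = FALSE)
    }
    if (length(rest_b)) {
      only_b[[length(only_b) + 1L]] <-
        data.frame(id = rest_b, kind = kind, stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, cols) {
    if (length(x)) do.call(rbind, x)
    else stats::setNames(as.data.frame(replicate(length(cols), character(),
                                                 simplify = FALSE),
                                       stringsAsFactors = FALSE), cols)
  }
  list(matched = bind(matched, c("id_a", "id_b", "kind")),
       only_in_a = bind(only_a, c("id", "kind")),
       only_in_b = bind(only_b, c("id", "kind")))
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

change_record <- function(subject_path, subject_kind, verb, subject,
                          old = NA_character_, new = NA_character_) {
  data.frame(subject_path = subject_path, subject_kind = subject_kind,
             verb = verb, subject = subject, old = old, new = new,
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(subject_path = character(), subject_kind = character(),
             verb = character(), subject = character(), old = character(),
             new = character(), stringsAsFactors = FALSE)
}

#' Attribute-level diff of a matched entity pair
#'
#' One record per attribute present on exactly one side (added/deleted) or
#' present on both with different values (updated). Attribute order never
#' produces a record. Annotation/notes subtree changes surface as records of
#' kind `annotation`.
#'
#' @param ea,eb matched entities (same kind) from the two versions
#' @return data.frame of change records
#' @export
diff_attributes <- function(ea, eb) {
  aa <- ea$attributes; ab <- eb$attributes
  rows <- list()
  path <- eb$path %||% ea$path
  rec_kind <- function(key) {
    if (key %in% .RESERVED_ATTR_KEYS) "annotation" else "attribute"
  }
  for (key in union(names(aa), names(ab))) {
    in_a <- key %in% names(aa); in_b <- key %in% names(ab)
    label <- sub("^\\.", "", key)
    if (in_a && in_b) {
      if (!identical(aa[[key]], ab[[key]])) {
        rows[[length(rows) + 1L]] <- change_record(
          path, rec_kind(key), "updated", label, aa[[key]], ab[[key]])
      }
    } else if (in_a) {
      rows[[length(rows) + 1L]] <- change_record(
        path, rec_kind(key), "deleted", label, old = aa[[key]])
    } else {
      rows[[length(rows) + 1L]] <- change_record(
        path, rec_kind(key), "added", label, new = ab[[key]])
    }
  }
  if (!length(rows)) return(empty_records())
  do.call(rbind, rows)
}

#' Participant diff of a matched reaction pair
#'
#' Works on the set of (species, role) pairs: a role change yields one
#' deleted record for the old role link plus one added record for the new;
#' one-sided presence yields a single record; a stoichiometry change on an
#' otherwise stable participant yields an updated record.
#'
#' @param ra,rb matched reactions
#' @return data.frame of change records
#' @export
diff_participants <- function(ra, rb) {
  parts <- function(r) {
    ps <- c(r$reactants, r$products, r$modifiers)
    if (!length(ps)) {
      return(data.frame(species = character(), role = character(),
                        stoich = numeric(), stringsAsFactors = FALSE))
    }
    data.frame(species = vapply(ps, `[[`, "", "species"),
               role = vapply(ps, `[[`, "", "role"),
               stoich = vapply(ps, `[[`, 0, "stoichiometry"),
               stringsAsFactors = FALSE)
  }
  pa <- parts(ra); pb <- parts(rb)
  all_a <- c(ra$reactants, ra$products, ra$modifiers)
  all_b <- c(rb$reactants, rb$products, rb$modifiers)
  key <- function(d) paste(d$species, d$role)
  path <- rb$path %||% ra$path
  rows <- list()
  for (i in seq_len(nrow(pa))) {
    if (!(key(pa)[i] %in% key(pb))) {
      rows[[length(rows) + 1L]] <- change_record(
        path, "participant", "deleted",
        sprintf("%s (%s)", pa$species[i], pa$role[i]), old = pa$role[i])
    }
  }
  for (i in seq_len(nrow(pb))) {
    k <- key(pb)[i]
    j <- match(k, key(pa))
    if (is.na(j)) {
      rows[[length(rows) + 1L]] <- change_record(
        path, "participant", "added",
        sprintf("%s (%s)", pb$species[i], pb$role[i]), new = pb$role[i])
    } else {
      if (!identical(pa$stoich[j], pb$stoich[i]) &&
          !(is.na(pa$stoich[j]) && is.na(pb$stoich[i]))) {
        rows[[length(rows) + 1L]] <- change_record(
          path, "participant", "updated",
          sprintf("%s (%s) stoichiometry", pb$species[i], pb$role[i]),
          old = format(pa$stoich[j]), new = format(pb$stoich[i]))
      }
      # other sub-node attribute changes (e.g. metaid on a speciesReference)
      drop <- c("stoichiometry", .RESERVED_ATTR_KEYS)
      aa <- all_a[[j]]$attributes; ab <- all_b[[i]]$attributes
      aa <- aa[!(names(aa) %in% drop)]; ab <- ab[!(names(ab) %in% drop)]
      if (!attrs_equal(aa, ab)) {
        rows[[length(rows) + 1L]] <- change_record(
          path, "sub_node", "updated",
          sprintf("speciesReference %s (%s)", pb$species[i], pb$role[i]),
          paste(sprintf("%s=%s", names(aa), aa), collapse = " "),
          paste(sprintf("%s=%s", names(ab), ab), collapse = " "))
      }
    }
  }
  if (!length(rows)) return(empty_records())
  do.call(rbind, rows)
}

#' Kinetic-law diff of a matched reaction pair
#'
#' Canonicalised content-MathML trees are compared structurally; differing
#' laws yield one updated record holding both sides rendered as infix text.
#' Local-parameter differences yield attribute-style records. A law that
#' cannot be interpreted yields an `updated`/`unparseable` record, never an
#' exception.
#'
#' @param la,lb kinetic laws (either may be NULL)
#' @param path XML path used for the records
#' @return data.frame of change records
#' @export
diff_kinetic_law <- function(la, lb, path = NA_character_) {
  rows <- list()
  if (is.null(la) && is.null(lb)) return(empty_records())
  if (is.null(la) || is.null(lb)) {
    present <- if (is.null(la)) lb else la
    verb <- if (is.null(la)) "added" else "deleted"
    txt <- tryCatch(math_to_infix(present$math), error = function(e) "unparseable")
    rows[[1L]] <- change_record(path, "kinetic_law", verb, "kineticLaw",
                                old = if (verb == "deleted") txt else NA_character_,
                                new = if (verb == "added") txt else NA_character_)
    return(do.call(rbind, rows))
  }
  cmp <- tryCatch(math_equal(la$math, lb$math), error = function(e) NA)
  if (is.na(cmp)) {
    rows[[length(rows) + 1L]] <- change_record(
      path, "kinetic_law", "updated", "kineticLaw", "unparseable", "unparseable")
  } else if (!cmp) {
    old_txt <- tryCatch(math_to_infix(la$math), error = function(e) "unparseable")
    new_txt <- tryCatch(math_to_infix(lb$math), error = function(e) "unparseable")
    rows[[length(rows) + 1L]] <- change_record(
      path, "kinetic_law", "updated", "kineticLaw", old_txt, new_txt)
  }
  pa <- la$local_parameters; pb <- lb$local_parameters
  for (id in union(names(pa), names(pb))) {
    in_a <- id %in% names(pa); in_b <- id %in% names(pb)
    if (in_a && in_b) {
      if (!attrs_equal(pa[[id]], pb[[id]])) {
        rows[[length(rows) + 1L]] <- change_record(
          path, "sub_node", "updated", sprintf("localParameter %s", id),
          paste(sprintf("%s=%s", names(pa[[id]]), pa[[id]]), collapse = " "),
          paste(sprintf("%s=%s", names(pb[[id]]), pb[[id]]), collapse = " "))
      }
    } else {
      rows[[length(rows) + 1L]] <- change_record(
        path, "sub_node", if (in_b) "added" else "deleted",
        sprintf("localParameter %s", id),
        old = if (in_a) paste(sprintf("%s=%s", names(pa[[id]]), pa[[id]]),
                              collapse = " ") else NA_character_,
        new = if (in_b) paste(sprintf("%s=%s", names(pb[[id]]), pb[[id]]),
                              collapse = " ") else NA_character_)
    }
  }
  if (!length(rows)) return(empty_records())
  do.call(rbind, rows)
}

entity_key <- function(kind, id) paste0(kind, ":", id)

#' Classify every entity of two model versions into a change class
#'
#' Composes [map_entities()] with the attribute, participant and kinetic-law
#' diffs. Unmatched entities become `insert`/`delete`; matched entities with
#' at least one change record become `update`, otherwise `none`. Matched,
#' content-equal entities whose XML path differs between the documents are
#' recorded in the move-path map (old path to new path) but keep class
#' `none`: document moves have no influence on the network level.
#'
#' @param a,b `sbml_model` objects (old and new version)
#' @return object of class `change_set`: list with `mapping`, `class_of`
#'   (named character, `kind:id` keys), `records_of` (named list of record
#'   data.frames), `move_path_map` (named character)
#' @export
classify <- function(a, b) {
  mapping <- map_entities(a, b)
  class_of <- character()
  records_of <- list()
  move_map <- character()
  mt <- mapping$matched
  for (i in seq_len(nrow(mt))) {
    kind <- mt$kind[i]
    ea <- model_entity(a, kind, mt$id_a[i])
    eb <- model_entity(b, kind, mt$id_b[i])
    recs <- diff_attributes(ea, eb)
    if (kind == "reaction") {
      recs <- rbind(recs,
                    diff_participants(ea, eb),
                    diff_kinetic_law(ea$kinetic_law, eb$kinetic_law,
                                     path = eb$path))
    }
    key <- entity_key(kind, mt$id_b[i])
    records_of[[key]] <- recs
    if (nrow(recs)) {
      class_of[[key]] <- "update"
    } else {
      class_of[[key]] <- "none"
      if (!identical(ea$path, eb$path)) move_map[[ea$path]] <- eb$path
    }
  }
  for (i in seq_len(nrow(mapping$only_in_a))) {
    key <- entity_key(mapping$only_in_a$kind[i], mapping$only_in_a$id[i])
    class_of[[key]] <- "delete"
    records_of[[key]] <- empty_records()
  }
  for (i in seq_len(nrow(mapping$only_in_b))) {
    key <- entity_key(mapping$only_in_b$kind[i], mapping$only_in_b$id[i])
    class_of[[key]] <- "insert"
    records_of[[key]] <- empty_records()
  }
  structure(list(mapping = mapping, class_of = class_of,
                 records_of = records_of, move_path_map = move_map),
            class = "change_set")
}

#' @export
print.change_set <- function(x, ...) {
  tab <- table(factor(x$class_of,
                      levels = c("insert", "delete", "update", "none")))
  cat("<change_set>\n")
  print(tab)
  invisible(x)
}

#' Human-readable change report for one entity
#'
#' Returns the entity's change records with annotation-subtree records
#' filtered out (they are detected but not displayed, to keep reports clear),
#' moved paths rewritten against the move-path map so every path refers to
#' the new document, and a rendered `text` column. Records follow document
#' order of the new version.
#'
#' @param cs a `change_set`
#' @param entity_id entity id, optionally prefixed `kind:`
#' @return data.frame of display records with a `text` column
#' @export
change_report <- function(cs, entity_id) {
  stopifnot(inherits(cs, "change_set"))
  key <- if (grepl(":", entity_id, fixed = TRUE)) entity_id else {
    hits <- grep(paste0(":", entity_id, "$"), names(cs$class_of), value = TRUE)
    if (length(hits) != 1L) {
      stop_sbgndiff("sbgndiff_lookup_error", "unknown entity id: %s", entity_id)
    }
    hits
  }
  if (!(key %in% names(cs$class_of))) {
    stop_sbgndiff("sbgndiff_lookup_error", "unknown entity id: %s", entity_id)
  }
  recs <- cs$records_of[[key]] %||% empty_records()
  if (is.null(recs)) recs <- empty_records()
  recs <- recs[recs$subject_kind != "annotation", , drop = FALSE]
  if (nrow(recs)) {
    moved <- recs$subject_path %in% names(cs$move_path_map)
    recs$subject_path[moved] <- cs$move_path_map[recs$subject_path[moved]]
    recs <- recs[order(recs$subject_path, recs$subject), , drop = FALSE]
    recs$text <- vapply(seq_len(nrow(recs)), function(i) {
      r <- recs[i, ]
      detail <- if (r$verb == "updated") {
        sprintf("'%s' -> '%s'", r$old, r$new)
      } else if (r$verb == "added") sprintf("'%s'", r$new)
      else if (!is.na(r$old)) sprintf("'%s'", r$old) else ""
      trimws(sprintf("%s %s %s", r$subject, r$verb, detail))
    }, "")
  } else {
    recs$text <- character()
  }
  rownames(recs) <- NULL
  recs
}
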