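#' Check referential integrity of a condensed model
#'
#' Findings are data, not exceptions: one row per dangling reference
#' (species to compartment, reaction participant to species, compartment to
#' enclosing compartment) and one per cycle in the compartment hierarchy.
#' An empty result means the model is referentially closed.
#'
#' @param m an `sbml_model`
#' @return data.frame with columns `finding`, `entity`, `ref`, `message`
#' @export
validate_references <- function(m) {
  stopifnot(inherits(m, "sbml_model"))
  comp_ids <- entity_ids(m$compartments)
  sp_ids <- entity_ids(m$species)
  rows <- list()
  add <- function(finding, entity, ref, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      finding = finding, entity = entity, ref = ref, message = message,
      stringsAsFactors = FALSE)
  }
  for (s in m$species) {
    if (!is.na(s$compartment) && !(s$compartment %in% comp_ids)) {
      add("dangling_compartment", s$id, s$compartment,
          sprintf("species '%s' refers to unknown compartment '%s'",
                  s$id, s$compartment))
    }
  }
  for (r in m$reactions) {
    for (p in c(r$reactants, r$products, r$modifiers)) {
      if (!(p$species %in% sp_ids)) {
        add("dangling_species", r$id, p$species,
            sprintf("reaction '%s' %s refers to unknown species '%s'",
                    r$id, p$role, p$species))
      }
    }
    if (!is.na(r$compartment) && !(r$compartment %in% comp_ids)) {
      add("dangling_compartment", r$id, r$compartment,
          sprintf("reaction '%s' refers to unknown compartment '%s'",
                  r$id, r$compartment))
    }
  }
  parent_of <- stats::setNames(
    vapply(m$compartments, `[[`, "", "parent"), comp_ids)
  for (cid in comp_ids) {
    p <- parent_of[[cid]]
    if (!is.na(p) && !(p %in% comp_ids)) {
      add("dangling_parent", cid, p,
          sprintf("compartment '%s' refers to unknown parent '%s'", cid, p))
    }
  }
  # cycle detection over the parent forest
  for (cid in comp_ids) {
    seen <- character()
    cur <- cid
    while (!is.na(cur) && cur %in% comp_ids) {
      if (cur %in% seen) {
        cyc <- seen[which(seen == cur):length(seen)]
        if (identical(min(cyc), cid)) {   # report each cycle once
          add("parent_cycle", cid, paste(cyc, collapse = ","),
              sprintf("compartment parent cycle: %s",
                      paste(cyc, collapse = " -> ")))
        }
        break
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  if (!length(rows)) {
    return(data.frame(finding = character(), entity = character(),
                      ref = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
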