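#' Condensed SBML model objects
#'
#' An `sbml_model` is the condensed, network-relevant view of one SBML
#' document: the three lists of compartments, species and reactions, each
#' entity carrying its full attribute map verbatim plus the fields that drive
#' the visualisation (`id`, `name`, `compartment`, `sboTerm`). The XML path of
#' every entity in the source document is recorded so that changes can be
#' reported against document positions (and moves detected).
#'
#' Reserved attribute-map keys `.annotation` and `.notes` hold the canonical
#' serialisation of the entity's annotation/notes subtrees; their change is
#' detectable but their content is never interpreted.
#'
#' @name sbml_model
#' @keywords internal
NULL

.RESERVED_ATTR_KEYS <- c(".annotation", ".notes")

new_sbml_model <- function(model_id, compartments = list(), species = list(),
                           reactions = list()) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  m <- structure(
    list(
      model_id = model_id,
      compartments = compartments,
      species = species,
      reactions = reactions
    ),
    class = "sbml_model"
  )
  validate_sbml_model(m)
}

new_compartment <- function(id, name = NA_character_, parent = NA_character_,
                            attributes = character(), path = NA_character_) {
  list(id = id, name = name, parent = parent,
       attributes = attributes, path = path)
}

new_species <- function(id, name = NA_character_, compartment = NA_character_,
                        sbo_term = NA_character_, attributes = character(),
                        path = NA_character_) {
  if (!is.na(sbo_term) && !grepl("^SBO:[0-9]{7}$", sbo_term)) {
    stop("invalid sboTerm accession: ", sbo_term, call. = FALSE)
  }
  list(id = id, name = name, compartment = compartment, sbo_term = sbo_term,
       attributes = attributes, path = path)
}

new_participant <- function(species_id, role,
                            sbo_term = NA_character_,
                            stoichiometry = NA_real_,
                            attributes = character()) {
  role <- match.arg(role, c("reactant", "product", "modifier"))
  list(species = species_id, role = role, sbo_term = sbo_term,
       stoichiometry = stoichiometry, attributes = attributes)
}

new_kinetic_law <- function(math = NULL, local_parameters = list()) {
  list(math = math, local_parameters = local_parameters)
}

new_reaction <- function(id, name = NA_character_, compartment = NA_character_,
                         sbo_term = NA_character_, reversible = FALSE,
                         reactants = list(), products = list(),
                         modifiers = list(), kinetic_law = NULL,
                         attributes = character(), path = NA_character_) {
  list(id = id, name = name, compartment = compartment, sbo_term = sbo_term,
       reversible = isTRUE(reversible), reactants = reactants,
       products = products, modifiers = modifiers, kinetic_law = kinetic_law,
       attributes = attributes, path = path)
}

#' Validate structural invariants of a condensed model
#'
#' Checks id uniqueness across all entity kinds and basic field shapes.
#' Referential integrity across entities is checked separately by
#' [validate_references()], which returns findings rather than failing.
#'
#' @param m an `sbml_model`
#' @return `m`, invisibly-checked (errors on violation)
#' @keywords internal
validate_sbml_model <- function(m) {
  ids <- c(vapply(m$compartments, `[[`, "", "id"),
           vapply(m$species, `[[`, "", "id"),
           vapply(m$reactions, `[[`, "", "id"))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate entity id in model: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m
}

entity_ids <- function(entities) vapply(entities, `[[`, "", "id")

model_entity <- function(m, kind, id) {
  pool <- switch(kind,
                 compartment = m$compartments,
                 species = m$species,
                 reaction = m$reactions,
                 stop("unknown entity kind: ", kind, call. = FALSE))
  hit <- which(entity_ids(pool) == id)
  if (!length(hit)) return(NULL)
  pool[[hit[1L]]]
}

#' Index of entity XML paths
#'
#' @param m an `sbml_model`
#' @return named character vector, `kind:id` -> XML path in the source document
#' @export
document_path_index <- function(m) {
  stopifnot(inherits(m, "sbml_model"))
  out <- character()
  for (kind in c("compartment", "species", "reaction")) {
    pool <- switch(kind, compartment = m$compartments,
                   species = m$species, reaction = m$reactions)
    for (e in pool) out[paste0(kind, ":", e$id)] <- e$path
  }
  out
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model '%s': %d compartments, %d species, %d reactions>\n",
              x$model_id, length(x$compartments), length(x$species),
              length(x$reactions)))
  invisible(x)
}

# attribute maps are named character vectors; equality ignores order
attrs_equal <- function(a, b) {
  if (!length(a) || !length(b)) return(length(a) == length(b))
  a <- a[order(names(a))]
  b <- b[order(names(b))]
  identical(names(a), names(b)) && all(a == b)
}
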