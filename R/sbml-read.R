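#' Parse an SBML document into the condensed model
#'
#' Reads the network-relevant subset of an SBML Level 2 or Level 3 document:
#' the lists of compartments, species and reactions, with every attribute
#' preserved verbatim, participants resolved by species id, the kinetic law
#' (if any) canonicalised from content MathML, and the XML path of each entity
#' recorded. Annotation and notes subtrees are captured as opaque canonical
#' strings under the reserved attribute keys `.annotation` and `.notes`.
#'
#' @param x file path, or a character string containing an SBML document
#' @return an object of class `sbml_model`
#' @examples
#' m <- read_sbml(generate_base_model(3, 1, 1, sbo_coverage = 1, seed = 1))
#' m
#' @export
read_sbml <- function(x) {
  doc <- tryCatch(
    {
      if (length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
        if (!file.exists(x)) {
          stop_sbgndiff("sbgndiff_input_error", "file not found: %s", x)
        }
        xml2::read_xml(x)
      } else {
        xml2::read_xml(paste(x, collapse = "\n"))
      }
    },
    error = function(e) {
      if (inherits(e, "sbgndiff_error")) stop(e)
      # xml2 error messages carry the libxml line/column diagnostics
      stop_sbgndiff("sbgndiff_parse_error", "malformed XML: %s",
                    conditionMessage(e))
    }
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop_sbgndiff("sbgndiff_format_error",
                  "not an SBML document (root element is <%s>)",
                  xml2::xml_name(root))
  }
  model_node <- find_child(root, "model")
  if (is.null(model_node)) {
    stop_sbgndiff("sbgndiff_format_error", "SBML document has no <model>")
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  comps <- lapply(list_children(model_node, "listOfCompartments", "compartment"),
                  parse_compartment)
  specs <- lapply(list_children(model_node, "listOfSpecies", "species"),
                  parse_species)
  rxns <- lapply(list_children(model_node, "listOfReactions", "reaction"),
                 parse_reaction)
  tryCatch(
    new_sbml_model(model_id, comps, specs, rxns),
    error = function(e) {
      stop_sbgndiff("sbgndiff_integrity_error", "%s", conditionMessage(e))
    }
  )
}

find_child <- function(node, name) {
  hits <- xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", name))
  if (!length(hits)) NULL else hits[[1L]]
}

list_children <- function(node, list_name, item_name) {
  lst <- find_child(node, list_name)
  if (is.null(lst)) return(list())
  as.list(xml2::xml_find_all(lst, sprintf("./*[local-name()='%s']", item_name)))
}

# readable XML path: element names plus 1-based index among same-name siblings
entity_path <- function(node) {
  parts <- character()
  cur <- node
  repeat {
    nm <- xml2::xml_name(cur)
    parent <- tryCatch(xml2::xml_parent(cur), error = function(e) NULL)
    if (is.null(parent) || inherits(parent, "xml_missing") ||
        !nzchar(xml2::xml_name(parent))) {
      parts <- c(paste0("/", nm), parts)
      break
    }
    sibs <- xml2::xml_find_all(parent, sprintf("./*[local-name()='%s']", nm))
    k <- which(vapply(as.list(sibs), identical, TRUE, y = cur))
    parts <- c(if (length(sibs) > 1L) sprintf("%s[%d]", nm, k[1L]) else nm,
               parts)
    cur <- parent
  }
  paste(parts, collapse = "/")
}

# every XML attribute verbatim, plus annotation/notes as canonical strings
entity_attributes <- function(node) {
  at <- xml2::xml_attrs(node)
  for (sub in c("annotation", "notes")) {
    child <- find_child(node, sub)
    if (!is.null(child)) {
      at[[paste0(".", sub)]] <- canonical_xml_string(child)
    }
  }
  at
}

# opaque canonical form of a subtree: inter-element whitespace collapsed
canonical_xml_string <- function(node) {
  s <- as.character(node)
  s <- gsub(">[[:space:]]+<", "><", s)
  trimws(s)
}

parse_compartment <- function(node) {
  at <- entity_attributes(node)
  new_compartment(
    id = req_attr(node, "id"),
    name = attr_or_na(at, "name"),
    parent = attr_or_na(at, "outside"),
    attributes = at,
    path = entity_path(node)
  )
}

parse_species <- function(node) {
  at <- entity_attributes(node)
  new_species(
    id = req_attr(node, "id"),
    name = attr_or_na(at, "name"),
    compartment = attr_or_na(at, "compartment"),
    sbo_term = attr_or_na(at, "sboTerm"),
    attributes = at,
    path = entity_path(node)
  )
}

parse_reaction <- function(node) {
  at <- entity_attributes(node)
  rev_attr <- attr_or_na(at, "reversible")
  new_reaction(
    id = req_attr(node, "id"),
    name = attr_or_na(at, "name"),
    compartment = attr_or_na(at, "compartment"),
    sbo_term = attr_or_na(at, "sboTerm"),
    # SBML Level 2 semantics: reversible defaults to true when absent
    reversible = if (is.na(rev_attr)) TRUE else identical(rev_attr, "true"),
    reactants = parse_participants(node, "listOfReactants", "reactant"),
    products = parse_participants(node, "listOfProducts", "product"),
    modifiers = parse_participants(node, "listOfModifiers", "modifier"),
    kinetic_law = parse_kinetic_law(node),
    attributes = at,
    path = entity_path(node)
  )
}

parse_participants <- function(rxn_node, list_name, role) {
  item <- if (role == "modifier") "modifierSpeciesReference" else "speciesReference"
  nodes <- list_children(rxn_node, list_name, item)
  lapply(nodes, function(n) {
    at <- entity_attributes(n)
    st <- attr_or_na(at, "stoichiometry")
    new_participant(
      species_id = req_attr(n, "species"),
      role = role,
      sbo_term = attr_or_na(at, "sboTerm"),
      stoichiometry = if (is.na(st)) NA_real_ else as.numeric(st),
      attributes = at
    )
  })
}

parse_kinetic_law <- function(rxn_node) {
  kl <- find_child(rxn_node, "kineticLaw")
  if (is.null(kl)) return(NULL)
  math_node_xml <- find_child(kl, "math")
  math <- if (is.null(math_node_xml)) NULL else canonicalise_mathml(math_node_xml)
  params <- list()
  for (list_name in c("listOfParameters", "listOfLocalParameters")) {
    for (item in c("parameter", "localParameter")) {
      for (p in list_children(kl, list_name, item)) {
        params[[xml2::xml_attr(p, "id")]] <- xml2::xml_attrs(p)
      }
    }
  }
  new_kinetic_law(math = math, local_parameters = params)
}

req_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) {
    v <- xml2::xml_attr(node, "species")  # tolerated only for participants
  }
  if (is.na(v)) {
    stop_sbgndiff("sbgndiff_format_error", "<%s> element missing '%s'",
                  xml2::xml_name(node), name)
  }
  v
}

attr_or_na <- function(at, name) {
  if (name %in% names(at)) at[[name]] else NA_character_
}
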