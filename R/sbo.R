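#' SBO term to SBGN glyph / arc resolution
#'
#' No official SBO-to-SBGN mapping exists, so the package fixes one: a small
#' table anchors glyph and modulation-arc classes at specific SBO terms, and
#' every other term inherits the class of its nearest mapped ancestor in a
#' packaged snapshot of the SBO is-a hierarchy. Terms that reach the root
#' without hitting a mapped ancestor fall back to the SBGN defaults
#' (`unspecified-entity` for glyphs, `modulation` for modifier arcs).
#'
#' @name sbo_mapping
NULL

GLYPH_CLASSES <- c("unspecified-entity", "simple-chemical", "macromolecule",
                   "nucleic-acid-feature", "complex", "empty-set", "process",
                   "compartment")

ARC_CLASSES <- c("consumption", "production", "modulation", "stimulation",
                 "catalysis", "inhibition", "necessary-stimulation")

.SBO_GLYPH_MAP <- c(
  "SBO:0000247" = "simple-chemical",
  "SBO:0000245" = "macromolecule",
  "SBO:0000250" = "nucleic-acid-feature",
  "SBO:0000251" = "nucleic-acid-feature",
  "SBO:0000253" = "complex",
  "SBO:0000291" = "empty-set",
  "SBO:0000285" = "unspecified-entity",
  "SBO:0000375" = "process"
)

.SBO_MODULATION_MAP <- c(
  "SBO:0000013" = "catalysis",
  "SBO:0000020" = "inhibition",
  "SBO:0000459" = "stimulation",
  "SBO:0000461" = "necessary-stimulation",
  "SBO:0000019" = "modulation"
)

.sbo_cache <- new.env(parent = emptyenv())

#' Parent lookup table of the packaged SBO hierarchy snapshot
#'
#' @return named character vector, child accession -> parent accession
#' @export
sbo_parents <- function() {
  if (is.null(.sbo_cache$parents)) {
    path <- system.file("extdata", "sbo-parents.tsv", package = "sbgndiff",
                        mustWork = TRUE)
    tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                             col.names = c("child", "parent"),
                             stringsAsFactors = FALSE)
    .sbo_cache$parents <- stats::setNames(tab$parent, tab$child)
  }
  .sbo_cache$parents
}

check_sbo_accession <- function(sbo_term) {
  if (!grepl("^SBO:[0-9]{7}$", sbo_term)) {
    stop_sbgndiff("sbgndiff_format_error",
                  "invalid SBO accession: '%s' (expected SBO: + 7 digits)",
                  sbo_term)
  }
  sbo_term
}

# walk child -> parent until a term of `map` is hit; NA when none is
sbo_resolve <- function(sbo_term, map) {
  parents <- sbo_parents()
  cur <- sbo_term
  seen <- character()
  while (!is.na(cur) && !(cur %in% seen)) {
    if (cur %in% names(map)) return(map[[cur]])
    seen <- c(seen, cur)
    cur <- if (cur %in% names(parents)) parents[[cur]] else NA_character_
  }
  NA_character_
}

#' Glyph class for an SBO term
#'
#' @param sbo_term SBO accession (`SBO:NNNNNNN`) or NA/NULL
#' @return glyph class string; `unspecified-entity` for absent or unmapped
#'   terms
#' @examples
#' sbo_to_glyph("SBO:0000247")   # simple chemical
#' sbo_to_glyph("SBO:0000327")   # inherits from its simple-chemical parent
#' sbo_to_glyph(NA)              # the SBGN default
#' @export
sbo_to_glyph <- function(sbo_term) {
  if (is.null(sbo_term) || is.na(sbo_term)) return("unspecified-entity")
  check_sbo_accession(sbo_term)
  hit <- sbo_resolve(sbo_term, .SBO_GLYPH_MAP)
  if (is.na(hit)) "unspecified-entity" else hit
}

#' Arc class for a participant role and SBO term
#'
#' Reactants and products force `consumption` / `production` regardless of
#' term; modifiers resolve through the modulation subtree, defaulting to
#' plain `modulation`.
#'
#' @param role one of `reactant`, `product`, `modifier`
#' @param sbo_term optional SBO accession of the modifier link
#' @return arc class string
#' @export
sbo_to_arc <- function(role, sbo_term = NA_character_) {
  if (!(length(role) == 1L && role %in% c("reactant", "product", "modifier"))) {
    stop_sbgndiff("sbgndiff_format_error", "invalid participant role: '%s'",
                  paste(role, collapse = ","))
  }
  if (role == "reactant") return("consumption")
  if (role == "product") return("production")
  if (is.null(sbo_term) || is.na(sbo_term)) return("modulation")
  check_sbo_accession(sbo_term)
  hit <- sbo_resolve(sbo_term, .SBO_MODULATION_MAP)
  if (is.na(hit)) "modulation" else hit
}
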