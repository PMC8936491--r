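# hand-built SBML snippets and independent oracles used across the suite

sbml_doc <- function(body, model_id = "m") {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
         '  <model id="', model_id, '">\n', body, '  </model>\n</sbml>\n')
}

# the canonical one-reaction model: X -> Y
xy_model <- function() {
  sbml_doc(paste0(
    '    <listOfCompartments><compartment id="c1" name="cell"/></listOfCompartments>\n',
    '    <listOfSpecies>\n',
    '      <species id="X" name="Species X" compartment="c1"/>\n',
    '      <species id="Y" name="Species Y" compartment="c1"/>\n',
    '    </listOfSpecies>\n',
    '    <listOfReactions>\n',
    '      <reaction id="r1" reversible="false">\n',
    '        <listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>\n',
    '        <listOfProducts><speciesReference species="Y" stoichiometry="1"/></listOfProducts>\n',
    '      </reaction>\n',
    '    </listOfReactions>\n'))
}

# strip document-position bookkeeping so models can be compared field-by-field
strip_paths <- function(m) {
  wipe <- function(es) lapply(es, function(e) { e$path <- NA_character_; e })
  m$compartments <- wipe(m$compartments)
  m$species <- wipe(m$species)
  m$reactions <- wipe(m$reactions)
  m
}

# reserialise a parsed model with every attribute map reversed and altered
# indentation, to probe attribute-order / whitespace robustness
reserialise_shuffled <- function(text) {
  m <- read_sbml(text)
  shuffle <- function(es) lapply(es, function(e) {
    e$attributes <- rev(e$attributes)
    e
  })
  m$compartments <- shuffle(m$compartments)
  m$species <- shuffle(m$species)
  m$reactions <- lapply(m$reactions, function(r) {
    r$attributes <- rev(r$attributes)
    r$reactants <- lapply(r$reactants, function(p) { p$attributes <- rev(p$attributes); p })
    r$products <- lapply(r$products, function(p) { p$attributes <- rev(p$attributes); p })
    r$modifiers <- lapply(r$modifiers, function(p) { p$attributes <- rev(p$attributes); p })
    r
  })
  gsub("\n  ", "\n      ", write_sbml(m))   # altered indentation
}

# --- independent line-marching boundary oracle -----------------------------
# vectorised inside/outside predicates written separately from the package's
# analytic intersection code
oracle_inside <- function(glyph, px, py, centre, size) {
  x <- px - centre[1]; y <- py - centre[2]
  w2 <- size[1] / 2; h2 <- size[2] / 2
  r015 <- 0.15 * min(size)
  switch(glyph,
    "unspecified-entity" = (x / w2)^2 + (y / h2)^2 <= 1,
    "empty-set" = x^2 + y^2 <= min(w2, h2)^2,
    "simple-chemical" = {
      r <- min(w2, h2)
      dx <- pmax(abs(x) - pmax(w2 - r, 0), 0)
      dy <- pmax(abs(y) - pmax(h2 - r, 0), 0)
      dx^2 + dy^2 <= r^2
    },
    "macromolecule" = ,
    "nucleic-acid-feature" = {
      inside_rect <- abs(x) <= w2 & abs(y) <= h2
      dx <- abs(x) - (w2 - r015); dy <- abs(y) - (h2 - r015)
      corner <- dx > 0 & dy > 0
      inside_rect & (!corner | (dx^2 + dy^2 <= r015^2))
    },
    "complex" = abs(x) <= w2 & abs(y) <= h2 & (abs(x) + abs(y)) <= (w2 + h2 - r015),
    "process" = abs(x) <= w2 & abs(y) <= h2,
    stop("oracle: unknown glyph ", glyph)
  )
}

march_boundary <- function(glyph, centre, size, origin, step = 0.01) {
  d <- centre - origin
  len <- sqrt(sum(d^2))
  n <- max(2L, ceiling(len / step))
  t <- seq(0, 1, length.out = n)
  px <- origin[1] + t * d[1]; py <- origin[2] + t * d[2]
  inside <- oracle_inside(glyph, px, py, centre, size)
  k <- which(inside)[1]
  if (is.na(k)) return(c(NA_real_, NA_real_))
  c(px[k], py[k])
}

# --- minimal standalone SBGN-ML reader (round-trip oracle) -----------------
read_sbgnml_summary <- function(text) {
  doc <- xml2::read_xml(text)
  glyphs <- xml2::xml_find_all(doc, ".//*[local-name()='glyph']")
  arcs <- xml2::xml_find_all(doc, ".//*[local-name()='arc']")
  bb <- xml2::xml_find_all(doc, ".//*[local-name()='glyph']/*[local-name()='bbox']")
  bbox <- data.frame(
    id = xml2::xml_attr(xml2::xml_parent(bb), "id"),
    x = as.numeric(xml2::xml_attr(bb, "x")),
    y = as.numeric(xml2::xml_attr(bb, "y")),
    w = as.numeric(xml2::xml_attr(bb, "w")),
    h = as.numeric(xml2::xml_attr(bb, "h")),
    stringsAsFactors = FALSE)
  styles <- xml2::xml_find_all(doc, ".//*[local-name()='style']")
  list(
    n_glyphs = length(glyphs),
    n_arcs = length(arcs),
    glyph_ids = xml2::xml_attr(glyphs, "id"),
    arc_ids = xml2::xml_attr(arcs, "id"),
    bbox = bbox,
    style_ids = xml2::xml_attr(styles, "id"),
    style_members = lapply(styles, function(s) {
      strsplit(xml2::xml_attr(s, "idList"), " ", fixed = TRUE)[[1]]
    })
  )
}

# small fixture pair factory used by several files
make_fixture <- function(seed, n_species = 12, n_reactions = 6,
                         n_compartments = 3, n_mutations = 5) {
  base <- generate_base_model(n_species, n_reactions, n_compartments,
                              sbo_coverage = 0.5, seed = seed)
  mutate(base, n_mutations, seed = seed + 10000L)
}
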