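Package: sbgndiff
Title: Network-Level Visualisation of Differences Between SBML Model Versions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes a semantics-aware diff between two versions of an
    SBML-encoded biochemical model, classifies every compartment, species and
    reaction into one of four change classes (insert, delete, update, move),
    maps the result onto a unified SBGN Process Description graph, lays the
    graph out with a deterministic force-directed simulation plus geometric
    post-processing (compartment bounding boxes, parallel-arc bending,
    arrow-head placement on glyph boundaries), and exports the coloured
    difference map as JSON, SVG and SBGN-ML with render-extension styles and
    COMODI change annotations. Includes a synthetic fixture generator that
    produces model version pairs with ground-truth mutation logs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
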