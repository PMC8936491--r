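---
title: "Visualising differences between SBML model versions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualising differences between SBML model versions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgndiff)
```

## The problem

Biochemical models encoded in SBML evolve: curation, extension and format
migration produce successive versions of the same model. A line-based diff of
the XML misreads this history — reordered attributes or shifted whitespace
show up as deletions and insertions, and two versions of the same species are
reported as unrelated. What a modeller actually wants to see is the change at
the *network* level: which species, reactions and compartments appeared,
vanished, or changed, drawn on the reaction network itself.

`sbgndiff` computes a structure-aware diff between two SBML documents, maps
it onto a single SBGN Process Description (PD) graph containing both
versions, lays that graph out deterministically, and exports it as
interchange JSON, SVG and SBGN-ML with colour-coded change highlighting.

## The condensed model and the diff

Only the network-relevant subset of SBML is interpreted: the lists of
compartments, species and reactions, each entity's full attribute map, the
participant lists (reactants, products, modifiers), and the kinetic law.
Annotation and notes subtrees are captured as opaque canonical strings so
that *changes* to them are detected while their content is never
interpreted. Because the diff operates on this parsed structure, attribute
order and whitespace can never produce a change.

Entities of the two versions are mapped by id within their kind; entities
left unpaired are then matched by side-unique name (ids occasionally change
across published versions while names persist — the fallback covers that
case without any structural similarity scoring, which we deliberately keep
out of scope). Every element then receives exactly one change class:

* **insert** (green) — present only in the new version,
* **delete** (red) — present only in the old version,
* **update** (yellow) — mapped, with at least one attribute, participant,
  kinetic-law or annotation change,
* **none** (black) — mapped and unchanged.

Pure document *moves* — an element whose content is identical but whose XML
path differs, e.g. after sibling reordering — keep class `none`: they have
no network-level effect. They are recorded in a move-path map so that change
reports always cite paths valid in the *new* document.

Update granularity is deliberately coarse on the network: any non-empty
change-record list colours the mapped element yellow, and reaction sub-node
changes (participants, local parameters, kinetic law, speciesReference
metaids) attach to the reaction's process node. The per-entity records
themselves stay fine-grained and are retrievable with `change_report()`.

Kinetic laws are compared as canonicalised content-MathML trees (namespace
prefixes dropped, whitespace-only text removed, child order kept — content
MathML is order-significant; the canonicalisation is idempotent). Differing
laws are reported once, rendered as normalised infix text on both sides; a
law that cannot be interpreted degrades to an `unparseable` record, never an
exception.

## From diff to SBGN PD graph

SBML reactions relate species directly; SBGN PD is bipartite. Each reaction
therefore becomes a *process node*, and every participant contributes one
arc: reactant → consumption into the process, product → production out of
it, modifier → a modulation-family arc. A reaction whose reactant (or
product) list is empty in both versions gains a source/sink (empty set) node
so the process remains well-formed. The graph is the *union* of both
versions: a deleted reaction keeps its (red) process node and arcs while its
species persist. A participant role change materialises exactly as the
visual idiom of the tool this package follows: one deleted arc for the old
role plus one inserted arc for the new role.

Glyphs and arrow heads are selected from SBO terms. Since no official
SBO-to-SBGN mapping exists, the package fixes one: anchor terms
(simple chemical SBO:0000247, macromolecule SBO:0000245, nucleic-acid
feature SBO:0000250/251, complex SBO:0000253, empty set SBO:0000291,
unspecified entity SBO:0000285; catalysis SBO:0000013, inhibition
SBO:0000020, stimulation SBO:0000459, necessary stimulation SBO:0000461,
modulation SBO:0000019) plus nearest-mapped-ancestor inheritance over a
packaged snapshot of the SBO is-a hierarchy (`inst/extdata/sbo-parents.tsv`,
a flat child–parent list restricted to the relevant branches, so no network
access is ever needed). Unmapped or absent terms fall back to the SBGN
defaults. Process nodes are serialised with SBO:0000375 so that the JSON
interchange round-trips without a separate node-kind attribute.

The interchange JSON has two arrays, `nodes` and `links`; node attributes
`id` (required), `label`, `compartment`, `sboTerm`, `bivesChange`; link
attributes `source`, `target` (required), `class`, `bivesClass`. Change
attributes are omitted for unchanged elements. Compartment nodes carry an
`isCompartment` extension attribute (the format explicitly allows extra
attributes). A JSON-Schema document ships under `inst/schema/`; because no
JSON-Schema validator package is available to R here, `from_json()` enforces
the schema's rules directly in code and rejects dangling links and unknown
vocabulary values.

## Layout

Positions come from a damped force simulation: pairwise many-body repulsion
(`repulsion_strength / d` velocity increments, default 150), springs toward
a rest length per link (default 80 px, stiffness 0.3), and a rigid centring
step that moves the centroid to the canvas centre each tick. Forces are
scaled by a temperature `alpha` that starts at 1 and decays by a factor
`1 − 0.0228` per tick until it falls below `0.001` (at most 300 ticks), so
the system provably cools; the velocity-damped integration uses a 0.4
velocity-decay per tick. These schedule constants mirror common
force-simulation defaults; every one of them is overridable via
`layout_params()` or a flat `key=value` config file.

Two choices make the layout reproducible enough to test bit-for-bit:

* initial positions lie on a deterministic phyllotaxis spiral — the seed
  only rotates its phase, so no tolerance for random jitter is needed;
* the simulation is plain sequential arithmetic, so identical inputs and
  seed give identical geometry on one platform.

For a two-node graph the stationary distance satisfies the closed-form force
balance `spring_strength · (d − rest) = repulsion_strength / d`; the test
suite checks convergence to the numeric root within 10%.

Three geometric post-processing steps follow:

1. **Compartment boxes.** Compartments are processed children-before-parents;
   each axis-aligned box is the min/max over member-node extents and child
   boxes, padded by 15 px, and drawn parents-first so children paint on top.
   An empty compartment degenerates to a fixed minimum box at the canvas
   centre (with a message). Process nodes participate when the reaction
   carries a `compartment` attribute.
2. **Parallel-arc bending.** Links sharing an unordered endpoint pair are
   drawn as circular arcs with distinct signed bend ranks: a single link is
   straight; an even group of 2k links gets ranks ±1…±k; an odd group keeps
   exactly one straight link. The sagitta is `|rank| × 25 px` — a fixed bend
   per rank, chosen because inter-node distances are not fixed under a force
   layout. Rank order follows a stable sort by arc class, change class and
   declaration order, so the assignment is deterministic.
3. **Arrow heads.** Heads placed at a fixed radius from the target centre
   overlap non-circular glyphs, so each head-bearing arc (production and the
   modulation family; consumption carries no head and is skipped) anchors at
   the analytic crossing point between its incoming direction and the target
   outline. Glyphs decompose into primitives — stadium/circle, rounded
   rectangle, octagon, ellipse, square — with corner radii and cuts fixed at
   15% of the smaller node dimension. Bent arcs use the circular arc's
   tangent at the target as the approach direction. The tests verify anchors
   against an independent line-marching oracle (0.01 px steps) to within
   0.5 px over 1000 randomised cases.

Ports are omitted entirely: under a force layout the species connected to a
process scatter around it, and pinning their arcs to two ports forces edge
crossings without adding information. This trades a minor SBGN PD
compatibility point for a clearer drawing.

## Export

SVG output paints compartment boxes, then arcs (bends as elliptical-arc path
segments, heads as shared marker definitions referenced per arc), then
glyphs with labels; stroke colours follow the change-class scheme
(red/green/yellow/black by default, fully overridable through a style file —
e.g. for colour-blind-safe palettes). SBGN-ML 0.2 output carries one glyph
per node with its bounding box, one arc per link with the arrow-head anchor
as end point, a render-extension block defining one style per change class
with the coloured element ids, and — because SBGN itself has no difference
semantics — a COMODI annotation (Insertion/Deletion/Update IRIs) on every
changed element so other tools can interpret the encoded changes. PNG export
delegates to an external rasteriser when one is present and otherwise fails
with a clear capability error.

## The synthetic-fixture generator

`generate_base_model()` emulates the condensed structure the pipeline
consumes: a random compartment forest, species assigned to compartments
(with a configurable fraction carrying SBO terms drawn from the mapping
tables), and reactions wiring 1–3 reactants, 1–3 products and 0–2 modifiers,
with kinetic laws on about half the reactions. `mutate()` applies randomly
chosen, mutually consistent mutations — entity insertion and deletion,
attribute updates, participant role changes, kinetic-law edits, and
sibling-order moves — each touching a previously untouched subject, so the
returned log maps one-to-one onto expected change classes
(`mutation_log_classes()`); deletions only ever pick unreferenced subjects,
keeping both documents referentially closed.

What the generator does *not* emulate: real curation histories (id renames
with annotation churn, unit changes, SBML level migrations), models with
rules, events or function definitions, and very large maps. Passing tests
therefore demonstrate correctness of the diff/translation/layout machinery
on well-formed condensed models, not robustness to every artefact found in
public model repositories.

## Problem sizes and numerical choices

The test battery uses 100 generated version pairs of 12 species, 6 reactions
and 3 compartments with 5 mutations each — large enough to exercise every
mutation kind and the union graph, small enough that the whole suite runs in
well under a minute. Degenerate inputs are handled explicitly: empty graphs
lay out to empty geometry, coincident nodes get a deterministic minimum
separation in the repulsion kernel, zero-length chords skip arrow-head
placement, and a ray origin inside a glyph raises a containment error rather
than returning a spurious anchor.

## Known limitations

* CellML is not supported; the diff assumes SBML Level 2/3 documents.
* Only the condensed subset is diffed — rules, events, function definitions
  and SBML packages (layout, comp, fbc) are outside the contract.
* The name-fallback matching is intentionally minimal; systematic id renames
  without stable names will appear as delete+insert pairs.
* Reversible reactions are drawn as ordinary consumption/production (the
  double-port reversibility notation is excluded along with ports).
* Layout quality degrades on disease-map-scale graphs; the force simulation
  is quadratic in the node count and makes no attempt at global
  edge-crossing minimisation.
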