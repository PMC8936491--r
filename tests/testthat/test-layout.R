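two_node_graph <- function() {
  nodes <- data.frame(
    id = c("x", "p"), label = c("x", "p"), compartment = NA_character_,
    sbo = c(NA, "SBO:0000375"), glyph = c("unspecified-entity", "process"),
    change = "none", kind = c("entity", "process"), stringsAsFactors = FALSE)
  links <- data.frame(source = "x", target = "p", arc_class = "consumption",
                      change = "none", stringsAsFactors = FALSE)
  sbgndiff:::new_diff_graph(nodes, links)
}

test_that("a single node settles at the canvas centre", {
  g <- two_node_graph()
  g$nodes <- g$nodes[1, , drop = FALSE]; g$links <- g$links[0, , drop = FALSE]
  p <- layout_params(seed = 5)
  geo <- run_layout(g, p)
  expect_lt(abs(geo$positions$x - p$canvas_width / 2), 1)
  expect_lt(abs(geo$positions$y - p$canvas_height / 2), 1)
})

test_that("the simulation is deterministic for identical input and seed", {
  fp <- make_fixture(3)
  a <- read_sbml(fp$model_a); b <- read_sbml(fp$model_b)
  g <- build_network(a, b, classify(a, b))
  p <- layout_params(seed = 99)
  expect_identical(run_layout(g, p), run_layout(g, p))
  # a different seed gives a different (rotated) configuration
  geo2 <- run_layout(g, layout_params(seed = 100))
  expect_false(identical(geo2$positions, run_layout(g, p)$positions))
})

test_that("two linked nodes converge to the force-balance distance", {
  g <- two_node_graph()
  p <- layout_params(seed = 1)
  geo <- run_layout(g, p)
  d <- sqrt(sum((as.numeric(geo$positions[1, c("x", "y")]) -
                 as.numeric(geo$positions[2, c("x", "y")]))^2))
  # oracle: numeric root of spring/repulsion balance
  balance <- function(r) {
    p$spring_strength * (r - p$link_rest_length) - p$repulsion_strength / r
  }
  eq <- stats::uniroot(balance, c(p$link_rest_length,
                                  10 * p$link_rest_length))$root
  expect_lt(abs(d - eq) / eq, 0.10)
})

test_that("kinetic energy is non-increasing while the simulation cools", {
  fp <- make_fixture(8)
  a <- read_sbml(fp$model_a); b <- read_sbml(fp$model_b)
  g <- build_network(a, b, classify(a, b))
  geo <- run_layout(g, layout_params(seed = 2))
  e <- geo$energy
  tail_e <- utils::tail(e, ceiling(length(e) * 0.1))
  expect_true(all(diff(tail_e) <= 1e-9))
})

test_that("an empty graph lays out to empty geometry", {
  eg <- sbgndiff:::new_diff_graph(sbgndiff:::empty_nodes(),
                                  sbgndiff:::empty_links())
  geo <- run_layout(eg, layout_params())
  expect_identical(nrow(geo$positions), 0L)
  expect_identical(nrow(geo$bends), 0L)
})

test_that("a compartment box is the padded extent of its members", {
  nodes <- data.frame(
    id = c("n1", "c"), label = c("n1", "c"),
    compartment = c("c", NA), sbo = NA_character_,
    glyph = c("macromolecule", "compartment"), change = "none",
    kind = c("entity", "compartment"), stringsAsFactors = FALSE)
  g <- sbgndiff:::new_diff_graph(nodes, sbgndiff:::empty_links())
  geo <- structure(list(
    positions = data.frame(id = "n1", x = 100, y = 100,
                           stringsAsFactors = FALSE),
    sizes = data.frame(id = "n1", w = 40, h = 30, stringsAsFactors = FALSE)),
    class = "geometry")
  b <- compute_compartment_boxes(g, geo, padding = 10)
  expect_equal(c(b$x0, b$y0, b$x1, b$y1), c(70, 75, 130, 125))
})

test_that("nested compartment boxes contain members and children", {
  set.seed(404)
  for (rep in 1:5) {
    n <- 12
    nodes <- data.frame(
      id = sprintf("n%d", 1:n), label = "",
      compartment = sample(c("inner", "outer"), n, replace = TRUE),
      sbo = NA_character_, glyph = "macromolecule", change = "none",
      kind = "entity", stringsAsFactors = FALSE)
    comp <- data.frame(
      id = c("outer", "inner"), label = c("outer", "inner"),
      compartment = c(NA, "outer"), sbo = NA_character_,
      glyph = "compartment", change = "none", kind = "compartment",
      stringsAsFactors = FALSE)
    g <- sbgndiff:::new_diff_graph(rbind(comp, nodes),
                                   sbgndiff:::empty_links())
    geo <- structure(list(
      positions = data.frame(id = nodes$id, x = runif(n, 0, 800),
                             y = runif(n, 0, 500), stringsAsFactors = FALSE),
      sizes = data.frame(id = nodes$id, w = runif(n, 20, 60),
                         h = runif(n, 15, 40), stringsAsFactors = FALSE)),
      class = "geometry")
    pad <- 15
    b <- compute_compartment_boxes(g, geo, padding = pad)
    # oracle: brute-force min/max over member extents
    for (cid in c("inner", "outer")) {
      mem <- which(nodes$compartment == cid)
      xs <- c(geo$positions$x[mem] - geo$sizes$w[mem] / 2,
              geo$positions$x[mem] + geo$sizes$w[mem] / 2)
      ys <- c(geo$positions$y[mem] - geo$sizes$h[mem] / 2,
              geo$positions$y[mem] + geo$sizes$h[mem] / 2)
      row <- b[b$compartment_id == cid, ]
      if (cid == "inner") {
        expect_equal(row$x0, min(xs) - pad); expect_equal(row$x1, max(xs) + pad)
        expect_equal(row$y0, min(ys) - pad); expect_equal(row$y1, max(ys) + pad)
      } else {
        # outer must cover its own members plus the inner box (+ padding)
        inner <- b[b$compartment_id == "inner", ]
        expect_lte(row$x0, min(xs, inner$x0) - pad + 1e-9)
        expect_gte(row$x1, max(xs, inner$x1) + pad - 1e-9)
      }
      # containment of every member's full extent
      expect_true(all(geo$positions$x[mem] - geo$sizes$w[mem] / 2 >= row$x0))
      expect_true(all(geo$positions$x[mem] + geo$sizes$w[mem] / 2 <= row$x1))
    }
    inner <- b[b$compartment_id == "inner", ]
    outer <- b[b$compartment_id == "outer", ]
    expect_true(inner$x0 >= outer$x0 && inner$x1 <= outer$x1 &&
                inner$y0 >= outer$y0 && inner$y1 <= outer$y1)
    # draw order: parent painted before child
    expect_lt(which(b$compartment_id == "outer"),
              which(b$compartment_id == "inner"))
  }
})

test_that("an empty compartment degenerates to a fixed box with a message", {
  comp <- data.frame(id = "lonely", label = "lonely",
                     compartment = NA_character_, sbo = NA_character_,
                     glyph = "compartment", change = "none",
                     kind = "compartment", stringsAsFactors = FALSE)
  g <- sbgndiff:::new_diff_graph(comp, sbgndiff:::empty_links())
  geo <- structure(list(positions = data.frame(id = character(), x = numeric(),
                                               y = numeric()),
                        sizes = data.frame(id = character(), w = numeric(),
                                           h = numeric())),
                   class = "geometry")
  expect_message(b <- compute_compartment_boxes(g, geo, 10), "degenerate")
  expect_true(b$x1 > b$x0 && b$y1 > b$y0)
})

test_that("parallel-arc groups get distinct ranks, straight link iff odd", {
  mk_links <- function(n, flip = logical(n)) {
    data.frame(source = ifelse(flip, "p", "a"),
               target = ifelse(flip, "a", "p"),
               arc_class = rep(c("modulation", "stimulation", "catalysis",
                                 "inhibition", "necessary-stimulation",
                                 "modulation", "stimulation"), length.out = n),
               change = "none", stringsAsFactors = FALSE)
  }
  # oracle, enumerated by hand from the alternating-side rule
  expected_ranks <- list(`1` = 0L, `2` = c(-1L, 1L), `3` = c(-1L, 0L, 1L),
                         `4` = c(-2L, -1L, 1L, 2L),
                         `5` = c(-2L, -1L, 0L, 1L, 2L),
                         `6` = c(-3L, -2L, -1L, 1L, 2L, 3L),
                         `7` = c(-3L, -2L, -1L, 0L, 1L, 2L, 3L))
  for (n in 1:7) {
    bends <- assign_bends(mk_links(n), bend_unit = 25)
    expect_identical(sort(bends$rank), expected_ranks[[as.character(n)]])
    expect_identical(anyDuplicated(bends$rank), 0L)
    expect_identical(0L %in% bends$rank, n %% 2L == 1L)
    expect_equal(bends$sagitta, abs(bends$rank) * 25)
  }
  # reverse-direction links conflict too
  bends <- assign_bends(mk_links(2, flip = c(FALSE, TRUE)))
  expect_identical(sort(bends$rank), c(-1L, 1L))
  # independent pairs never share a group
  two <- data.frame(source = c("a", "b"), target = c("p", "p"),
                    arc_class = "modulation", change = "none",
                    stringsAsFactors = FALSE)
  expect_identical(assign_bends(two)$rank, c(0L, 0L))
})

test_that("boundary intersections hit axis-aligned landmarks exactly", {
  # circle (empty set): ray from directly left hits the west point
  hit <- glyph_boundary_intersection("empty-set", c(100, 50), c(30, 30),
                                     c(0, 50))
  expect_equal(hit, c(85, 50))
  # ellipse from directly above hits the north point
  hit <- glyph_boundary_intersection("unspecified-entity", c(100, 50),
                                     c(40, 24), c(100, -10))
  expect_equal(hit, c(100, 38))
  # square process from the east
  hit <- glyph_boundary_intersection("process", c(0, 0), c(18, 18), c(50, 0))
  expect_equal(hit, c(9, 0))
  # origin inside is a containment error
  expect_error(
    glyph_boundary_intersection("process", c(0, 0), c(18, 18), c(1, 1)),
    class = "sbgndiff_containment_error")
})

test_that("analytic intersections match the line-marching oracle", {
  set.seed(777)
  glyphs <- c("macromolecule", "complex", "simple-chemical",
              "unspecified-entity", "process", "empty-set",
              "nucleic-acid-feature")
  for (glyph in glyphs) {
    for (rep in 1:20) {
      centre <- c(runif(1, 40, 120), runif(1, 40, 120))
      size <- c(runif(1, 24, 60), runif(1, 18, 40))
      theta <- runif(1, 0, 2 * pi)
      origin <- centre + c(cos(theta), sin(theta)) * runif(1, 50, 90)
      if (point_in_glyph(glyph, origin, centre, size)) next
      got <- glyph_boundary_intersection(glyph, centre, size, origin)
      want <- march_boundary(glyph, centre, size, origin)
      expect_lt(sqrt(sum((got - want)^2)), 0.5)
    }
  }
})

test_that("arrow heads anchor on boundaries; consumption carries none", {
  m <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="S" sboTerm="SBO:0000247"/>',
    '<species id="P"/><species id="M"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r">\n',
    '      <listOfReactants><speciesReference species="S"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="P"/></listOfProducts>\n',
    '      <listOfModifiers><modifierSpeciesReference species="M"/></listOfModifiers>\n',
    "    </reaction></listOfReactions>\n")))
  g <- build_network(m, m, classify(m, m))
  geo <- run_layout(g, layout_params(seed = 4))
  heads <- geo$arrowheads
  cons <- which(g$links$arc_class == "consumption")
  expect_false(any(heads$link %in% cons))
  headed <- which(g$links$arc_class %in% c("production", "modulation"))
  expect_setequal(heads$link, headed)
  # anchors sit on the target outline: just inside one way, outside the other
  for (j in seq_len(nrow(heads))) {
    k <- heads$link[j]
    tgt <- g$links$target[k]
    i <- match(tgt, geo$positions$id)
    centre <- c(geo$positions$x[i], geo$positions$y[i])
    size <- c(geo$sizes$w[i], geo$sizes$h[i])
    glyph <- g$nodes$glyph[match(tgt, g$nodes$id)]
    anchor <- c(heads$x[j], heads$y[j])
    dir <- c(heads$dx[j], heads$dy[j])
    expect_true(point_in_glyph(glyph, anchor + dir * 0.5, centre, size))
    expect_false(point_in_glyph(glyph, anchor - dir * 0.5, centre, size))
  }
})

test_that("production into a circle from the left anchors on its west point", {
  nodes <- data.frame(
    id = c("p", "s"), label = "", compartment = NA_character_,
    sbo = c("SBO:0000375", "SBO:0000247"),
    glyph = c("process", "simple-chemical"), change = "none",
    kind = c("process", "entity"), stringsAsFactors = FALSE)
  links <- data.frame(source = "p", target = "s", arc_class = "production",
                      change = "none", stringsAsFactors = FALSE)
  g <- sbgndiff:::new_diff_graph(nodes, links)
  geo <- structure(list(
    positions = data.frame(id = c("p", "s"), x = c(0, 100), y = c(50, 50),
                           stringsAsFactors = FALSE),
    sizes = data.frame(id = c("p", "s"), w = c(18, 26), h = c(18, 26),
                       stringsAsFactors = FALSE)),
    class = "geometry")
  bends <- assign_bends(g$links)
  heads <- place_arrowheads(g, geo, bends)
  expect_equal(c(heads$x, heads$y), c(100 - 13, 50))
})

test_that("layout parameters load from key=value config files", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# layout overrides", "canvas_width=900", "bend_unit=30",
               "max_ticks=50"), cfg)
  p <- read_layout_config(cfg)
  expect_equal(p$canvas_width, 900)
  expect_equal(p$bend_unit, 30)
  expect_identical(p$max_ticks, 50L)
  writeLines("no_such_key=1", cfg)
  expect_error(read_layout_config(cfg), class = "sbgndiff_input_error")
})
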