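#' Deterministic force-directed layout
#'
#' Positions the non-compartment nodes of a difference graph with a damped
#' velocity-Verlet force simulation: pairwise many-body repulsion, spring
#' forces toward the link rest length, and a rigid centring step that keeps
#' the centroid at the canvas centre. Initial positions lie on a phyllotaxis
#' spiral whose phase is the only thing the seed perturbs, so identical
#' inputs and seed reproduce positions bit-for-bit on one platform.
#'
#' The per-tick temperature `alpha` decays geometrically and scales every
#' force, so the system cools into a static configuration; the simulation
#' stops when `alpha < alpha_min` or after `max_ticks` ticks.
#'
#' @param g a `diff_graph`
#' @param p a [layout_params()] object
#' @return object of class `geometry`: list with `positions` (id, x, y),
#'   `sizes` (id, w, h), `boxes` (compartment boxes), `bends` (parallel-arc
#'   bend assignments), `arrowheads` (per-link anchor points), and the
#'   per-tick kinetic `energy` trace
#' @examples
#' m <- read_sbml(generate_base_model(4, 2, 1, sbo_coverage = 0.5, seed = 3))
#' geo <- run_layout(build_network(m, m, classify(m, m)), layout_params())
#' head(geo$positions)
#' @export
run_layout <- function(g, p = layout_params()) {
  stopifnot(inherits(g, "diff_graph"), inherits(p, "layout_params"))
  sim_nodes <- g$nodes[g$nodes$kind != "compartment", , drop = FALSE]
  n <- nrow(sim_nodes)
  geo <- structure(list(positions = data.frame(id = character(), x = numeric(),
                                               y = numeric(),
                                               stringsAsFactors = FALSE),
                        sizes = data.frame(id = character(), w = numeric(),
                                           h = numeric(),
                                           stringsAsFactors = FALSE),
                        boxes = NULL, bends = NULL, arrowheads = NULL,
                        energy = numeric()),
                   class = "geometry")
  if (n == 0L) {
    geo$boxes <- compute_compartment_boxes(g, geo, p$compartment_padding, p)
    geo$bends <- assign_bends(g$links, p$bend_unit)
    geo$arrowheads <- place_arrowheads(g, geo, geo$bends)
    return(geo)
  }
  cx <- p$canvas_width / 2; cy <- p$canvas_height / 2

  # phyllotaxis spiral; the seed only shifts the phase
  phase <- 2 * pi * ((p$seed %% 997) / 997)
  idx <- seq_len(n) - 1L
  radius <- (p$node_base_size / 4) * sqrt(0.5 + idx)
  angle <- idx * pi * (3 - sqrt(5)) + phase
  x <- cx + radius * cos(angle)
  y <- cy + radius * sin(angle)
  vx <- numeric(n); vy <- numeric(n)

  li <- match(g$links$source, sim_nodes$id)
  lj <- match(g$links$target, sim_nodes$id)
  keep <- !is.na(li) & !is.na(lj)
  li <- li[keep]; lj <- lj[keep]

  alpha <- p$alpha_start
  energy <- numeric(0)
  damp <- 1 - p$velocity_decay
  for (tick in seq_len(p$max_ticks)) {
    if (alpha < p$alpha_min) break
    # many-body repulsion, O(n^2)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        dx <- x[(i + 1L):n] - x[i]
        dy <- y[(i + 1L):n] - y[i]
        d2 <- dx * dx + dy * dy
        d2[d2 < 1e-6] <- 1e-6
        w <- p$repulsion_strength * alpha / d2
        vx[(i + 1L):n] <- vx[(i + 1L):n] + dx * w
        vy[(i + 1L):n] <- vy[(i + 1L):n] + dy * w
        vx[i] <- vx[i] - sum(dx * w)
        vy[i] <- vy[i] - sum(dy * w)
      }
    }
    # springs toward the rest length
    if (length(li)) {
      dx <- x[lj] + vx[lj] - x[li] - vx[li]
      dy <- y[lj] + vy[lj] - y[li] - vy[li]
      d <- sqrt(dx * dx + dy * dy)
      d[d < 1e-6] <- 1e-6
      f <- (d - p$link_rest_length) / d * alpha * p$spring_strength
      for (k in seq_along(li)) {
        vx[lj[k]] <- vx[lj[k]] - dx[k] * f[k] / 2
        vy[lj[k]] <- vy[lj[k]] - dy[k] * f[k] / 2
        vx[li[k]] <- vx[li[k]] + dx[k] * f[k] / 2
        vy[li[k]] <- vy[li[k]] + dy[k] * f[k] / 2
      }
    }
    # damped integration
    vx <- vx * damp; vy <- vy * damp
    x <- x + vx; y <- y + vy
    # rigid centring: centroid to canvas centre
    x <- x - mean(x) + cx
    y <- y - mean(y) + cy
    energy <- c(energy, sum(vx * vx + vy * vy))
    alpha <- alpha * (1 - p$alpha_decay)
  }

  sizes <- t(vapply(seq_len(n), function(i) {
    glyph_size(sim_nodes$glyph[i], p$node_base_size)
  }, c(w = 0, h = 0)))
  geo$positions <- data.frame(id = sim_nodes$id, x = x, y = y,
                              stringsAsFactors = FALSE)
  geo$sizes <- data.frame(id = sim_nodes$id, w = sizes[, "w"],
                          h = sizes[, "h"], stringsAsFactors = FALSE)
  geo$energy <- energy
  geo$boxes <- compute_compartment_boxes(g, geo, p$compartment_padding, p)
  geo$bends <- assign_bends(g$links, p$bend_unit)
  geo$arrowheads <- place_arrowheads(g, geo, geo$bends)
  geo
}

# node extent per glyph class, keeping each symbol's usual aspect ratio
glyph_size <- function(glyph, base) {
  switch(glyph,
         process = c(w = 0.45 * base, h = 0.45 * base),
         `empty-set` = c(w = 0.55 * base, h = 0.55 * base),
         `simple-chemical` = c(w = 0.65 * base, h = 0.65 * base),
         complex = c(w = base, h = 0.75 * base),
         c(w = base, h = 0.6 * base))   # unspecified, macromolecule, NA feat.
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d node positions, %d compartment boxes, %d bends, %d arrow heads>\n",
              nrow(x$positions), NROW(x$boxes), NROW(x$bends),
              NROW(x$arrowheads)))
  invisible(x)
}
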