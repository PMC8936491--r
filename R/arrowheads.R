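#' Arrow-head placement on glyph boundaries
#'
#' Arrow heads drawn at a fixed radius from the target centre overlap the
#' diverse SBGN glyph shapes, so every head-bearing arc (production and the
#' modulation family; consumption carries no head and is skipped) gets its
#' anchor computed as the crossing point between the incoming direction and
#' the target glyph outline. Bent arcs use the tangent of the circular arc
#' at the target as the effective incoming direction.
#'
#' @param g a `diff_graph`
#' @param geo a `geometry` with positions/sizes filled
#' @param bends bend assignments from [assign_bends()]
#' @return data.frame `link` (row index), `x`, `y` (anchor), `dx`, `dy`
#'   (unit approach direction)
#' @export
place_arrowheads <- function(g, geo, bends) {
  out <- data.frame(link = integer(), x = numeric(), y = numeric(),
                    dx = numeric(), dy = numeric(), stringsAsFactors = FALSE)
  if (!NROW(g$links)) return(out)
  headed <- which(g$links$arc_class %in%
                    c("production", "modulation", "stimulation", "catalysis",
                      "inhibition", "necessary-stimulation"))
  pos <- function(id) {
    i <- match(id, geo$positions$id)
    c(geo$positions$x[i], geo$positions$y[i])
  }
  size_of <- function(id) {
    i <- match(id, geo$sizes$id)
    c(geo$sizes$w[i], geo$sizes$h[i])
  }
  glyph_of <- stats::setNames(g$nodes$glyph, g$nodes$id)
  rows <- list()
  for (k in headed) {
    src <- g$links$source[k]; tgt <- g$links$target[k]
    P0 <- pos(src); P1 <- pos(tgt)
    if (anyNA(P0) || anyNA(P1)) next
    size <- size_of(tgt)
    rank <- bends$rank[match(k, bends$link)]
    sag <- bends$sagitta[match(k, bends$link)]
    dir_in <- arc_approach_direction(P0, P1, rank, sag)
    if (anyNA(dir_in)) next
    # back the ray origin out along the approach direction until outside
    reach <- max(sqrt(sum((P1 - P0)^2)), sqrt(sum(size^2)))
    O <- P1 - dir_in * reach
    tries <- 0L
    while (point_in_glyph(glyph_of[[tgt]], O, P1, size) && tries < 5L) {
      reach <- reach * 2; O <- P1 - dir_in * reach; tries <- tries + 1L
    }
    anchor <- glyph_boundary_intersection(glyph_of[[tgt]], P1, size, O)
    rows[[length(rows) + 1L]] <- data.frame(
      link = k, x = anchor[1], y = anchor[2], dx = dir_in[1], dy = dir_in[2],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# unit direction of travel at the target: chord direction for straight
# links, the arc tangent at the end point for bent links
arc_approach_direction <- function(P0, P1, rank, sagitta) {
  chord <- P1 - P0
  clen <- sqrt(sum(chord^2))
  if (clen < 1e-9) return(c(NA_real_, NA_real_))
  u <- chord / clen
  if (is.na(rank) || rank == 0L || sagitta <= 0) return(u)
  n <- c(-u[2], u[1])                            # unit normal (CCW)
  s <- sagitta * sign(rank)
  R <- (clen^2 / 4 + s^2) / (2 * abs(s))
  M <- (P0 + P1) / 2
  centre <- M + n * (sign(s) * (abs(s) - R))     # arc circle centre
  radial <- P1 - centre
  tang <- c(-radial[2], radial[1])
  tang <- tang / sqrt(sum(tang^2))
  if (sum(tang * u) < 0) tang <- -tang           # keep the travel direction
  tang
}
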