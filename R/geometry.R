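#' Compartment bounding boxes
#'
#' Boxes are computed bottom-up (children before parents): each compartment's
#' box is the componentwise min/max over the extents of its member nodes and
#' the boxes of its child compartments, expanded by `padding`. The result is
#' returned in draw order — parents first, so they paint beneath their
#' children. A compartment with neither members nor children degenerates to
#' a fixed minimum-size box at the canvas centre (with a message).
#'
#' @param g a `diff_graph`
#' @param geo a `geometry` with positions and sizes filled in
#' @param padding box padding in px
#' @param p layout parameters (canvas size for the degenerate fallback)
#' @return data.frame `compartment_id`, `x0`, `y0`, `x1`, `y1`, `depth`
#' @export
compute_compartment_boxes <- function(g, geo, padding,
                                      p = layout_params()) {
  comp <- g$nodes[g$nodes$kind == "compartment", , drop = FALSE]
  if (!nrow(comp)) {
    return(data.frame(compartment_id = character(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  parent_of <- stats::setNames(comp$compartment, comp$id)
  depth_of <- function(id) {
    d <- 0L; cur <- parent_of[[id]]
    while (!is.na(cur) && cur %in% comp$id && d < nrow(comp)) {
      d <- d + 1L; cur <- parent_of[[cur]]
    }
    d
  }
  depths <- vapply(comp$id, depth_of, 0L)
  boxes <- list()
  members <- g$nodes[g$nodes$kind != "compartment", , drop = FALSE]
  # deepest first: children exist before their parent is processed
  for (cid in comp$id[order(depths, decreasing = TRUE)]) {
    xs <- numeric(); ys <- numeric()
    mem <- members$id[!is.na(members$compartment) & members$compartment == cid]
    for (mid in mem) {
      i <- match(mid, geo$positions$id)
      if (is.na(i)) next
      w2 <- geo$sizes$w[i] / 2; h2 <- geo$sizes$h[i] / 2
      xs <- c(xs, geo$positions$x[i] - w2, geo$positions$x[i] + w2)
      ys <- c(ys, geo$positions$y[i] - h2, geo$positions$y[i] + h2)
    }
    for (child in names(parent_of)[!is.na(parent_of) & parent_of == cid]) {
      if (!is.null(boxes[[child]])) {
        b <- boxes[[child]]
        xs <- c(xs, b["x0"], b["x1"]); ys <- c(ys, b["y0"], b["y1"])
      }
    }
    if (!length(xs)) {
      message(sprintf("compartment '%s' has no members; degenerate box", cid))
      half <- max(2 * padding, 20)
      boxes[[cid]] <- c(x0 = p$canvas_width / 2 - half,
                        y0 = p$canvas_height / 2 - half,
                        x1 = p$canvas_width / 2 + half,
                        y1 = p$canvas_height / 2 + half)
    } else {
      boxes[[cid]] <- c(x0 = min(xs) - padding, y0 = min(ys) - padding,
                        x1 = max(xs) + padding, y1 = max(ys) + padding)
    }
  }
  draw_order <- comp$id[order(depths)]        # parents painted first
  out <- do.call(rbind, lapply(draw_order, function(cid) {
    b <- boxes[[cid]]
    data.frame(compartment_id = cid, x0 = b[["x0"]], y0 = b[["y0"]],
               x1 = b[["x1"]], y1 = b[["y1"]],
               depth = depths[[match(cid, comp$id)]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bend assignment for parallel arcs
#'
#' Links sharing an unordered endpoint pair overlap when drawn straight.
#' Each parallel group receives distinct signed bend ranks: a single link is
#' straight (rank 0); an even group of size 2k gets ranks ±1..±k; an odd
#' group of size 2k+1 keeps one straight link plus ranks ±1..±k, so the bend
#' grows with every further pair of conflicting links. Rank order follows a
#' stable sort by (arc class, change class, declaration order). The sagitta
#' (perpendicular offset at the chord midpoint) is `|rank| * bend_unit`.
#'
#' @param links link data.frame of a `diff_graph`
#' @param bend_unit sagitta per rank, px
#' @return data.frame `link` (row index into `links`), `rank`, `sagitta`
#' @export
assign_bends <- function(links, bend_unit = 25) {
  if (!NROW(links)) {
    return(data.frame(link = integer(), rank = integer(), sagitta = numeric(),
                      stringsAsFactors = FALSE))
  }
  pair_key <- ifelse(links$source < links$target,
                     paste(links$source, links$target),
                     paste(links$target, links$source))
  out <- data.frame(link = seq_len(nrow(links)), rank = NA_integer_,
                    sagitta = NA_real_, stringsAsFactors = FALSE)
  for (key in unique(pair_key)) {
    rows <- which(pair_key == key)
    ord <- rows[order(links$arc_class[rows], links$change[rows], rows)]
    m <- length(ord)
    ranks <- if (m %% 2L == 1L) {
      k <- (m - 1L) %/% 2L
      c(0L, as.integer(rbind(seq_len(k), -seq_len(k))))
    } else {
      k <- m %/% 2L
      as.integer(rbind(seq_len(k), -seq_len(k)))
    }
    out$rank[ord] <- ranks[seq_len(m)]
  }
  out$sagitta <- abs(out$rank) * bend_unit
  out
}
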