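#' Scalable SVG outlines for SBGN PD glyphs and arrow heads
#'
#' Each glyph class maps to a parametric SVG path scaled by the node size,
#' mirroring the primitive decomposition used for boundary intersection;
#' each head-bearing arc class maps to a marker path drawn in a 10x10
#' marker viewport.
#'
#' @return `glyph_path_library()` returns a list with `glyphs` (functions of
#'   centre and size returning an SVG path `d` string) and `markers` (named
#'   list of marker definitions: `d` path, `fill` either a literal or
#'   `"stroke"` to inherit the arc colour)
#' @export
glyph_path_library <- function() {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  rect_path <- function(cx, cy, w2, h2, r = 0) {
    if (r <= 0) {
      return(sprintf("M %s %s H %s V %s H %s Z",
                     fmt(cx - w2), fmt(cy - h2), fmt(cx + w2), fmt(cy + h2),
                     fmt(cx - w2)))
    }
    paste(
      sprintf("M %s %s", fmt(cx - w2 + r), fmt(cy - h2)),
      sprintf("H %s A %s %s 0 0 1 %s %s", fmt(cx + w2 - r), fmt(r), fmt(r),
              fmt(cx + w2), fmt(cy - h2 + r)),
      sprintf("V %s A %s %s 0 0 1 %s %s", fmt(cy + h2 - r), fmt(r), fmt(r),
              fmt(cx + w2 - r), fmt(cy + h2)),
      sprintf("H %s A %s %s 0 0 1 %s %s", fmt(cx - w2 + r), fmt(r), fmt(r),
              fmt(cx - w2), fmt(cy + h2 - r)),
      sprintf("V %s A %s %s 0 0 1 %s %s Z", fmt(cy - h2 + r), fmt(r), fmt(r),
              fmt(cx - w2 + r), fmt(cy - h2)))
  }
  ellipse_path <- function(cx, cy, rx, ry) {
    paste(
      sprintf("M %s %s", fmt(cx - rx), fmt(cy)),
      sprintf("A %s %s 0 1 0 %s %s", fmt(rx), fmt(ry), fmt(cx + rx), fmt(cy)),
      sprintf("A %s %s 0 1 0 %s %s Z", fmt(rx), fmt(ry), fmt(cx - rx), fmt(cy)))
  }
  glyphs <- list(
    `unspecified-entity` = function(c_, s_) {
      ellipse_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2)
    },
    `simple-chemical` = function(c_, s_) {
      r <- min(s_) / 2
      rect_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2, r)
    },
    macromolecule = function(c_, s_) {
      rect_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2, CORNER_FRACTION * min(s_))
    },
    `nucleic-acid-feature` = function(c_, s_) {
      rect_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2, CORNER_FRACTION * min(s_))
    },
    complex = function(c_, s_) {
      w2 <- s_[1] / 2; h2 <- s_[2] / 2; cut <- CORNER_FRACTION * min(s_)
      v <- list(c(-w2 + cut, -h2), c(w2 - cut, -h2), c(w2, -h2 + cut),
                c(w2, h2 - cut), c(w2 - cut, h2), c(-w2 + cut, h2),
                c(-w2, h2 - cut), c(-w2, -h2 + cut))
      paste0("M ", paste(vapply(v, function(p) {
        paste(fmt(c_[1] + p[1]), fmt(c_[2] + p[2]))
      }, ""), collapse = " L "), " Z")
    },
    `empty-set` = function(c_, s_) {
      r <- min(s_) / 2
      paste(ellipse_path(c_[1], c_[2], r, r),
            sprintf("M %s %s L %s %s",
                    fmt(c_[1] - r * 0.7071), fmt(c_[2] + r * 0.7071),
                    fmt(c_[1] + r * 0.7071), fmt(c_[2] - r * 0.7071)))
    },
    process = function(c_, s_) {
      rect_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2)
    },
    compartment = function(c_, s_) {
      rect_path(c_[1], c_[2], s_[1] / 2, s_[2] / 2, 10)
    }
  )
  markers <- list(
    production = list(d = "M 0 0 L 10 5 L 0 10 Z", fill = "stroke"),
    modulation = list(d = "M 0 5 L 5 0 L 10 5 L 5 10 Z", fill = "#ffffff"),
    stimulation = list(d = "M 0 0 L 10 5 L 0 10 Z", fill = "#ffffff"),
    catalysis = list(d = "M 1 5 A 4 4 0 1 0 9 5 A 4 4 0 1 0 1 5 Z",
                     fill = "#ffffff"),
    inhibition = list(d = "M 8 0 L 10 0 L 10 10 L 8 10 Z", fill = "stroke"),
    `necessary-stimulation` = list(
      d = "M 0 0 L 2 0 L 2 10 L 0 10 Z M 3 0 L 10 5 L 3 10 Z",
      fill = "#ffffff")
  )
  list(glyphs = glyphs, markers = markers)
}
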