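#' Layout parameters
#'
#' Controls the force-directed simulation and the geometric post-processing.
#' All lengths are in px (origin top-left, y increasing downward, as in SVG).
#'
#' @param canvas_width,canvas_height canvas size in px
#' @param link_rest_length spring rest length per link, px
#' @param repulsion_strength many-body repulsion strength (dimensionless)
#' @param spring_strength spring stiffness (dimensionless)
#' @param alpha_start,alpha_decay,alpha_min simulation temperature schedule;
#'   alpha decays by a factor `1 - alpha_decay` per tick and the simulation
#'   stops when it drops below `alpha_min`
#' @param velocity_decay per-tick velocity damping fraction
#' @param max_ticks hard tick limit
#' @param seed integer; perturbs the phase of the deterministic phyllotaxis
#'   initial placement
#' @param bend_unit sagitta per bend rank for parallel arcs, px
#' @param compartment_padding padding around compartment contents, px
#' @param node_base_size reference node size, px
#' @return object of class `layout_params`
#' @export
layout_params <- function(canvas_width = 1200, canvas_height = 800,
                          link_rest_length = 80, repulsion_strength = 150,
                          spring_strength = 0.3, alpha_start = 1,
                          alpha_decay = 0.0228, alpha_min = 0.001,
                          velocity_decay = 0.4, max_ticks = 300, seed = 42L,
                          bend_unit = 25, compartment_padding = 15,
                          node_base_size = 40) {
  p <- list(canvas_width = canvas_width, canvas_height = canvas_height,
            link_rest_length = link_rest_length,
            repulsion_strength = repulsion_strength,
            spring_strength = spring_strength, alpha_start = alpha_start,
            alpha_decay = alpha_decay, alpha_min = alpha_min,
            velocity_decay = velocity_decay, max_ticks = as.integer(max_ticks),
            seed = as.integer(seed), bend_unit = bend_unit,
            compartment_padding = compartment_padding,
            node_base_size = node_base_size)
  stopifnot(p$canvas_width > 0, p$canvas_height > 0, p$link_rest_length > 0,
            p$bend_unit > 0, p$compartment_padding >= 0, p$node_base_size > 0,
            p$alpha_decay > 0, p$alpha_decay < 1, p$max_ticks >= 1)
  structure(p, class = "layout_params")
}

#' Read layout parameters from a flat key=value config file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path config file path
#' @param base parameters to override (default [layout_params()])
#' @return `layout_params`
#' @export
read_layout_config <- function(path, base = layout_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop_sbgndiff("sbgndiff_input_error", "bad config line: '%s'", ln)
    }
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!(key %in% names(base))) {
      stop_sbgndiff("sbgndiff_input_error", "unknown config key: '%s'", key)
    }
    base[[key]] <- if (key %in% c("max_ticks", "seed")) as.integer(val)
                   else as.numeric(val)
  }
  do.call(layout_params, unclass(base))
}
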