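#' Change-class colour scheme
#'
#' Default stroke colours: deletions red, insertions green, updates yellow,
#' unchanged black. Moves render like unchanged elements (they have no
#' network-level effect). The scheme is fully overridable — e.g. for
#' colour-blind-friendly palettes — via [read_style_file()] or by passing a
#' named vector.
#'
#' @param delete,insert,update,none hex stroke colours
#' @return named character vector of class `colour_scheme`
#' @export
colour_scheme <- function(delete = "#e41a1c", insert = "#4daf4a",
                          update = "#ffcc00", none = "#000000") {
  s <- c(delete = delete, insert = insert, update = update, none = none)
  if (!all(grepl("^#[0-9a-fA-F]{6}$", s))) {
    stop_sbgndiff("sbgndiff_input_error",
                  "colours must be 6-digit hex values, got: %s",
                  paste(s[!grepl("^#[0-9a-fA-F]{6}$", s)], collapse = ", "))
  }
  structure(s, class = "colour_scheme")
}

scheme_colour <- function(scheme, change) {
  if (change == "move") change <- "none"
  scheme[[change]]
}

#' Read a colour-scheme style file
#'
#' CSS-like `class: #rrggbb` lines mapping change classes to stroke colours;
#' unknown classes are rejected, missing ones keep their defaults.
#'
#' @param path style file path
#' @param base scheme to override
#' @return `colour_scheme`
#' @export
read_style_file <- function(path, base = colour_scheme()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- as.character(base)
  names(vals) <- names(base)
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop_sbgndiff("sbgndiff_input_error", "bad style line: '%s'", ln)
    }
    key <- trimws(kv[1L])
    if (!(key %in% names(vals))) {
      stop_sbgndiff("sbgndiff_input_error", "unknown change class: '%s'", key)
    }
    vals[[key]] <- sub(";$", "", trimws(kv[2L]))
  }
  do.call(colour_scheme, as.list(vals))
}
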