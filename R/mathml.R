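#' Content-MathML canonicalisation and rendering
#'
#' SBML kinetic laws are encoded as content MathML. For comparison the XML is
#' reduced to a canonical tree: namespace prefixes dropped, whitespace-only
#' text nodes removed, remaining text trimmed, child order kept (content
#' MathML is order-significant). Canonicalisation is idempotent because it is
#' defined on the tree form.
#'
#' @name mathml
#' @keywords internal
NULL

# canonical node: list(tag, attrs = named chr in document order, children,
# text = trimmed character or NA)
math_node <- function(tag, attrs = character(), children = list(),
                      text = NA_character_) {
  if (!length(attrs)) attrs <- character()    # normalise empty named vectors
  list(tag = tag, attrs = attrs, children = children, text = text)
}

#' Canonicalise a content-MathML element into a comparable tree
#'
#' @param node an `xml2` element (typically `<math>`) or a canonical tree
#' @return canonical tree (idempotent on its own output)
#' @export
canonicalise_mathml <- function(node) {
  if (is.list(node) && !inherits(node, "xml_node") &&
      all(c("tag", "attrs", "children") %in% names(node))) {
    # already canonical: re-canonicalising is the identity
    return(node)
  }
  stopifnot(inherits(node, "xml_node"))
  tag <- xml2::xml_name(node)           # xml_name drops the prefix
  at <- xml2::xml_attrs(node)
  at <- at[!grepl("^xmlns(:|$)", names(at))]   # namespace decls are not content
  names(at) <- sub("^.*:", "", names(at))
  kids <- xml2::xml_contents(node)
  children <- list()
  text <- NA_character_
  for (k in seq_along(kids)) {
    kid <- kids[[k]]
    if (inherits(kid, "xml_node") && xml2::xml_type(kid) == "element") {
      children[[length(children) + 1L]] <- canonicalise_mathml(kid)
    } else {
      txt <- trimws(as.character(xml2::xml_text(kid)))
      if (nzchar(txt)) text <- if (is.na(text)) txt else paste(text, txt)
    }
  }
  math_node(tag, at, children, text)
}

math_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (!identical(a$tag, b$tag)) return(FALSE)
  if (!identical(is.na(a$text), is.na(b$text))) return(FALSE)
  if (!is.na(a$text) && !identical(a$text, b$text)) return(FALSE)
  if (!attrs_equal(a$attrs, b$attrs)) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children)) {
    if (!math_equal(a$children[[i]], b$children[[i]])) return(FALSE)
  }
  TRUE
}

.INFIX_OPS <- c(plus = "+", minus = "-", times = "*", divide = "/",
                power = "^")

#' Render a canonical math tree as normalised infix text
#'
#' Used in change records so that kinetic-law updates are human readable
#' without presentation MathML.
#'
#' @param node canonical tree from [canonicalise_mathml()], or NULL
#' @return single character string (`""` for NULL)
#' @export
math_to_infix <- function(node) {
  if (is.null(node)) return("")
  tag <- node$tag
  if (tag == "math") {
    return(paste(vapply(node$children, math_to_infix, ""), collapse = "; "))
  }
  if (tag %in% c("ci", "cn", "csymbol")) {
    return(if (is.na(node$text)) "?" else node$text)
  }
  if (tag == "apply" && length(node$children)) {
    op <- node$children[[1L]]$tag
    args <- vapply(node$children[-1L], math_to_infix, "")
    if (op %in% names(.INFIX_OPS)) {
      if (op == "minus" && length(args) == 1L) {
        return(paste0("-", args))
      }
      return(paste0("(", paste(args, collapse = paste0(" ", .INFIX_OPS[[op]], " ")), ")"))
    }
    return(paste0(op, "(", paste(args, collapse = ", "), ")"))
  }
  # lambda, piecewise, constants (true/pi/...) and anything else: generic form
  if (!length(node$children)) return(tag)
  paste0(tag, "(",
         paste(vapply(node$children, math_to_infix, ""), collapse = ", "), ")")
}

# serialise a canonical tree back to content-MathML XML (for lossless
# round-trips of the condensed subset and for fixture generation)
math_to_xml_string <- function(node, mathns = FALSE) {
  if (is.null(node)) return("")
  at <- node$attrs
  if (mathns) at <- c(xmlns = "http://www.w3.org/1998/Math/MathML", at)
  attr_str <- if (length(at)) {
    paste0(" ", paste(sprintf('%s="%s"', names(at), xml_escape(at)),
                      collapse = " "))
  } else ""
  inner <- paste0(vapply(node$children, math_to_xml_string, ""), collapse = "")
  if (!is.na(node$text)) inner <- paste0(xml_escape(node$text), inner)
  if (nzchar(inner)) {
    paste0("<", node$tag, attr_str, ">", inner, "</", node$tag, ">")
  } else {
    paste0("<", node$tag, attr_str, "/>")
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}
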