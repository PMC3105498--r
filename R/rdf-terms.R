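# RDF terms are stored in a canonical character encoding:
#   IRIs      "<http://...>"
#   blanks    "_:b1"
#   literals  "\"lexical\"", "\"lexical\"@en", "\"lexical\"^^<datatype-iri>"
# The lexical form inside a literal is backslash-escaped (\\ \" \n \r \t).
# All triple-store internals operate on these strings, which makes joins and
# set operations plain character comparisons.

#' Build an IRI term
#'
#' @param x character vector of absolute IRIs (without angle brackets).
#' @return canonical IRI term strings.
#' @export
iri <- function(x) {
  stopifnot(is.character(x))
  if (any(grepl("[<>\" ]", x)))
    stop("IRI may not contain '<', '>', '\"' or spaces")
  paste0("<", x, ">")
}

#' Build a blank-node term
#' @param label blank node label (without the \code{_:} prefix).
#' @return canonical blank node term strings.
#' @export
blankNode <- function(label) paste0("_:", label)

escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescapeLiteral <- function(x) {
  # reverse of escapeLiteral; processes backslash escapes left to right
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "")[[1]]
    out <- character(0); i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", u = "\\u", nxt))
        i <- i + 2L
      } else {
        out <- c(out, chars[i]); i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a literal term
#'
#' @param value atomic vector; numbers become xsd:integer/xsd:double typed
#'   literals, logicals xsd:boolean, characters plain literals.
#' @param datatype optional datatype IRI (plain string, no angle brackets).
#' @param lang optional language tag (mutually exclusive with datatype).
#' @return canonical literal term strings.
#' @export
literal <- function(value, datatype = NULL, lang = NULL) {
  if (!is.null(datatype) && !is.null(lang))
    stop("a literal cannot carry both a datatype and a language tag")
  if (is.null(datatype) && is.null(lang)) {
    if (is.logical(value)) {
      datatype <- paste0(XSD, "boolean"); value <- tolower(as.character(value))
    } else if (is.integer(value)) {
      datatype <- paste0(XSD, "integer"); value <- as.character(value)
    } else if (is.numeric(value)) {
      datatype <- paste0(XSD, "double")
      value <- formatC(value, digits = 17, format = "g")
    }
  }
  base <- paste0("\"", escapeLiteral(as.character(value)), "\"")
  if (!is.null(lang)) return(paste0(base, "@", lang))
  if (!is.null(datatype)) return(paste0(base, "^^<", datatype, ">"))
  base
}

#' Typed decimal literal preserving the printed lexical form
#' @param x numeric vector.
#' @export
decimalLiteral <- function(x) {
  paste0("\"", formatC(x, digits = 17, format = "g"), "\"^^<", XSD, "decimal>")
}

#' @rdname termType
#' @export
isTermIRI <- function(term) startsWith(term, "<")
#' @rdname termType
#' @export
isTermBlank <- function(term) startsWith(term, "_:")
#' @rdname termType
#' @export
isTermLiteral <- function(term) startsWith(term, "\"")

#' Classify canonical RDF term strings
#' @param term canonical term strings.
#' @return "iri", "blank" or "literal".
#' @export
termType <- function(term) {
  ifelse(isTermIRI(term), "iri", ifelse(isTermBlank(term), "blank", "literal"))
}

#' Extract the IRI text from an IRI term
#' @param term canonical IRI term strings.
#' @export
iriValue <- function(term) {
  stopifnot(all(isTermIRI(term)))
  substr(term, 2L, nchar(term) - 1L)
}

# split a canonical literal into (lexical, datatype, lang)
literalParts <- function(term) {
  stopifnot(length(term) == 1L, isTermLiteral(term))
  chars <- strsplit(term, "")[[1]]
  i <- 2L
  while (i <= length(chars)) {
    if (chars[i] == "\\") { i <- i + 2L; next }
    if (chars[i] == "\"") break
    i <- i + 1L
  }
  lex <- substr(term, 2L, i - 1L)
  rest <- substr(term, i + 1L, nchar(term))
  dt <- NA_character_; lang <- NA_character_
  if (startsWith(rest, "^^<")) dt <- substr(rest, 4L, nchar(rest) - 1L)
  if (startsWith(rest, "@")) lang <- substr(rest, 2L, nchar(rest))
  list(lexical = unescapeLiteral(lex), datatype = dt, lang = lang)
}

#' Lexical value of a literal term
#' @param term canonical literal term strings.
#' @export
literalValue <- function(term)
  vapply(term, function(t) literalParts(t)$lexical, character(1),
         USE.NAMES = FALSE)

#' Datatype IRI of a literal term (NA when plain or language tagged)
#' @param term canonical literal term strings.
#' @export
literalDatatype <- function(term)
  vapply(term, function(t) literalParts(t)$datatype, character(1),
         USE.NAMES = FALSE)

#' Render a term for tabular export: IRIs and blanks verbatim without
#' brackets, literals as their lexical value.
#' @param term canonical term strings (NA allowed for unbound).
#' @export
termText <- function(term) {
  out <- term
  ok <- !is.na(term)
  out[ok & isTermIRI(term)] <- iriValue(term[ok & isTermIRI(term)])
  lit <- ok & isTermLiteral(term)
  out[lit] <- literalValue(term[lit])
  out
}

# numeric view of a term, NA when not a number
termNumeric <- function(term) {
  suppressWarnings(vapply(term, function(t) {
    if (is.na(t) || !isTermLiteral(t)) return(NA_real_)
    as.numeric(literalParts(t)$lexical)
  }, numeric(1), USE.NAMES = FALSE))
}
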