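# Turtle / Notation3 reading and writing.
#
# The supported syntax is the Turtle subset of N3: @prefix/@base, 'a',
# predicate lists with ';', object lists with ',', blank node labels and
# anonymous [] property lists, quoted literals with language tags or
# datatypes, and bare numeric/boolean literals. N3 rules, paths and
# collections are rejected with a clear message.

# --- tokenizer -------------------------------------------------------------

# Token types: IRIREF, PNAME, BLANK, STRING, LANGTAG, DTYPE, NUMBER, VAR,
# WORD (bare words: a/true/false and SPARQL keywords), PUNCT, OP, EOF.
rdfTokenize <- function(text, sparql = FALSE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  tokens <- vector("list", 256L); nt <- 0L
  pos <- 1L; n <- nchar(text); line <- 1L
  push <- function(type, value) {
    nt <<- nt + 1L
    tokens[[nt]] <<- list(type = type, value = value, line = line)
  }
  grab <- function(pattern) {
    m <- regexpr(pattern, substr(text, pos, n), perl = TRUE)
    if (m == 1L) {
      len <- attr(m, "match.length")
      tok <- substr(text, pos, pos + len - 1L)
      line <<- line + lengths(regmatches(tok, gregexpr("\n", tok, fixed = TRUE)))
      pos <<- pos + len
      tok
    } else NULL
  }
  while (pos <= n) {
    if (!is.null(grab("^([ \t\r\n]+|#[^\n]*)"))) next
    ch <- substr(text, pos, pos)
    if (ch == "<") {
      tok <- grab("^<[^<>\"{}|^`\\\\ \t\n]*>")
      if (!is.null(tok)) { push("IRIREF", substr(tok, 2L, nchar(tok) - 1L)); next }
      if (sparql) {
        tok <- grab("^<=|^<"); push("OP", tok); next
      }
      stop("Turtle parse error at line ", line, ": malformed IRI")
    }
    if (ch == "\"") {
      tok <- grab("^\"(\\\\.|[^\"\\\\\n])*\"")
      if (is.null(tok))
        stop("Turtle parse error at line ", line, ": unterminated string")
      push("STRING", substr(tok, 2L, nchar(tok) - 1L)); next
    }
    if (ch == "@") {
      tok <- grab("^@(prefix|base)\\b")
      if (!is.null(tok)) { push("WORD", tok); next }
      tok <- grab("^@[A-Za-z][A-Za-z0-9-]*")
      if (!is.null(tok)) { push("LANGTAG", substr(tok, 2L, nchar(tok))); next }
      stop("Turtle parse error at line ", line, ": stray '@'")
    }
    tok <- grab("^\\^\\^")
    if (!is.null(tok)) { push("DTYPE", tok); next }
    tok <- grab("^_:[A-Za-z][A-Za-z0-9_-]*")
    if (!is.null(tok)) { push("BLANK", substr(tok, 3L, nchar(tok))); next }
    if (sparql) {
      tok <- grab("^[?$][A-Za-z_][A-Za-z0-9_]*")
      if (!is.null(tok)) { push("VAR", substr(tok, 2L, nchar(tok))); next }
      tok <- grab("^(>=|!=|&&|\\|\\||[=>!*])")
      if (!is.null(tok)) { push("OP", tok); next }
    }
    tok <- grab("^[+-]?(\\d+\\.\\d*|\\.\\d+|\\d+)([eE][+-]?\\d+)?")
    if (!is.null(tok)) { push("NUMBER", tok); next }
    tok <- grab("^([A-Za-z][A-Za-z0-9_-]*)?:([A-Za-z0-9][A-Za-z0-9_-]*)?")
    if (!is.null(tok)) { push("PNAME", tok); next }
    tok <- grab("^[A-Za-z][A-Za-z0-9_]*")
    if (!is.null(tok)) { push("WORD", tok); next }
    tok <- grab("^[][;,.(){}]")
    if (!is.null(tok)) { push("PUNCT", tok); next }
    stop("parse error at line ", line, ": unexpected character '", ch, "'")
  }
  push("EOF", "")
  tokens[seq_len(nt)]
}

# simple cursor over a token list
tokenCursor <- function(tokens) {
  i <- 0L
  list(
    peek = function() tokens[[min(i + 1L, length(tokens))]],
    next_ = function() { i <<- min(i + 1L, length(tokens)); tokens[[i]] },
    expect = function(type, value = NULL) {
      tok <- tokens[[min(i + 1L, length(tokens))]]
      if (tok$type != type || (!is.null(value) && tok$value != value))
        stop("parse error at line ", tok$line, ": expected ",
             if (is.null(value)) type else value, ", got '", tok$value, "'")
      i <<- i + 1L
      tok
    })
}

resolveIRI <- function(ref, base) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref) || is.null(base) || !nzchar(base))
    ref
  else paste0(base, ref)
}

expandPName <- function(pname, prefixes, line) {
  parts <- regmatches(pname, regexec("^([^:]*):(.*)$", pname))[[1]]
  pfx <- parts[2]; local <- parts[3]
  ns <- prefixes[[pfx]]
  if (is.null(ns) || is.na(ns))
    stop("parse error at line ", line, ": undeclared prefix '", pfx, ":'")
  paste0(ns, local)
}

#' Parse a Turtle/Notation3 document into a TripleStore
#'
#' @param text the document, as a single string or a character vector of
#'   lines.
#' @param base base IRI used to resolve relative IRI references.
#' @return a \code{TripleStore} holding exactly the asserted triples, with
#'   the document's prefix declarations captured.
#' @examples
#' st <- parseRDF('@prefix ex: <http://example.org/> . ex:s ex:p "v" .')
#' tripleCount(st)
#' @export
parseRDF <- function(text, base = "") {
  cur <- tokenCursor(rdfTokenize(text))
  prefixes <- list()
  subj <- pred <- obj <- character(0)
  nblank <- 0L
  emit <- function(s, p, o) {
    subj[length(subj) + 1L] <<- s
    pred[length(pred) + 1L] <<- p
    obj[length(obj) + 1L] <<- o
  }
  freshBlank <- function() { nblank <<- nblank + 1L; blankNode(paste0("genid", nblank)) }

  parseTerm <- function(allowLiteral = TRUE) {
    tok <- cur$peek()
    if (tok$type == "IRIREF") { cur$next_(); return(iri(resolveIRI(tok$value, base))) }
    if (tok$type == "PNAME") { cur$next_(); return(iri(expandPName(tok$value, prefixes, tok$line))) }
    if (tok$type == "BLANK") { cur$next_(); return(blankNode(tok$value)) }
    if (tok$type == "PUNCT" && tok$value == "[") {
      cur$next_()
      b <- freshBlank()
      if (!(cur$peek()$type == "PUNCT" && cur$peek()$value == "]"))
        parsePredicateObjectList(b)
      cur$expect("PUNCT", "]")
      return(b)
    }
    if (tok$type == "PUNCT" && tok$value == "(")
      stop("parse error at line ", tok$line,
           ": RDF collections '(...)' are not supported")
    if (allowLiteral) {
      if (tok$type == "STRING") {
        cur$next_()
        lex <- unescapeLiteral(tok$value)
        nxt <- cur$peek()
        if (nxt$type == "LANGTAG") { cur$next_(); return(literal(lex, lang = nxt$value)) }
        if (nxt$type == "DTYPE") {
          cur$next_()
          dt <- cur$peek()
          dtIRI <- if (dt$type == "IRIREF") { cur$next_(); resolveIRI(dt$value, base) }
                   else if (dt$type == "PNAME") { cur$next_(); expandPName(dt$value, prefixes, dt$line) }
                   else stop("parse error at line ", dt$line, ": expected datatype IRI")
          return(literal(lex, datatype = dtIRI))
        }
        return(literal(lex))
      }
      if (tok$type == "NUMBER") {
        cur$next_()
        dt <- if (grepl("[eE]", tok$value)) "double"
              else if (grepl("\\.", tok$value)) "decimal" else "integer"
        return(paste0("\"", tok$value, "\"^^<", XSD, dt, ">"))
      }
      if (tok$type == "WORD" && tok$value %in% c("true", "false")) {
        cur$next_()
        return(literal(tok$value, datatype = paste0(XSD, "boolean")))
      }
    }
    stop("parse error at line ", tok$line, ": unexpected '", tok$value, "'")
  }

  parsePredicateObjectList <- function(s) {
    repeat {
      tok <- cur$peek()
      p <- if (tok$type == "WORD" && tok$value == "a") {
        cur$next_(); iri(paste0(RDF_NS, "type"))
      } else parseTerm(allowLiteral = FALSE)
      if (!isTermIRI(p))
        stop("parse error at line ", tok$line, ": predicate must be an IRI")
      repeat {
        emit(s, p, parseTerm())
        if (cur$peek()$type == "PUNCT" && cur$peek()$value == ",") cur$next_()
        else break
      }
      if (cur$peek()$type == "PUNCT" && cur$peek()$value == ";") {
        cur$next_()
        # tolerate trailing ';' before '.' or ']'
        nxt <- cur$peek()
        if (nxt$type == "PUNCT" && nxt$value %in% c(".", "]")) break
      } else break
    }
  }

  repeat {
    tok <- cur$peek()
    if (tok$type == "EOF") break
    if (tok$type == "WORD" && tok$value %in% c("@prefix", "@base")) {
      cur$next_()
      if (tok$value == "@prefix") {
        pn <- cur$expect("PNAME")
        pfx <- sub(":.*$", "", pn$value)
        ns <- cur$expect("IRIREF")
        prefixes[[pfx]] <- resolveIRI(ns$value, base)
      } else {
        ns <- cur$expect("IRIREF")
        base <- resolveIRI(ns$value, base)
      }
      cur$expect("PUNCT", ".")
      next
    }
    s <- parseTerm(allowLiteral = FALSE)
    # a bare "[ ... ] ." statement carries its triples already
    if (!(cur$peek()$type == "PUNCT" && cur$peek()$value == "."))
      parsePredicateObjectList(s)
    cur$expect("PUNCT", ".")
  }
  pf <- unlist(prefixes)
  if (is.null(pf)) pf <- character(0)
  tripleStore(subj, pred, obj, prefixes = pf)
}

# --- serializer ------------------------------------------------------------

compactIRI <- function(iriTerm, prefixes) {
  x <- iriValue(iriTerm)
  if (length(prefixes)) {
    ord <- order(nchar(prefixes), decreasing = TRUE)
    for (k in ord) {
      ns <- prefixes[[k]]
      if (startsWith(x, ns)) {
        local <- substr(x, nchar(ns) + 1L, nchar(x))
        if (grepl("^([A-Za-z0-9][A-Za-z0-9_-]*)?$", local))
          return(paste0(names(prefixes)[k], ":", local))
      }
    }
  }
  paste0("<", x, ">")
}

serializeTerm <- function(term, prefixes) {
  if (isTermIRI(term)) return(compactIRI(term, prefixes))
  if (isTermBlank(term)) return(term)
  parts <- literalParts(term)
  lex <- escapeLiteral(parts$lexical)
  if (!is.na(parts$lang)) return(paste0("\"", lex, "\"@", parts$lang))
  if (!is.na(parts$datatype))
    return(paste0("\"", lex, "\"^^", compactIRI(iri(parts$datatype), prefixes)))
  paste0("\"", lex, "\"")
}

#' Serialize a TripleStore as Turtle
#'
#' Prefix declarations are emitted as \code{@prefix} lines; triples are
#' grouped per subject using ';' and ','. The output re-parses to a store
#' isomorphic to the input.
#'
#' @param store a \code{TripleStore}.
#' @param path optional file to write to (UTF-8).
#' @return the document as a single string (invisibly when \code{path} is
#'   given).
#' @export
serializeRDF <- function(store, path = NULL) {
  pf <- store@prefixes
  lines <- character(0)
  if (length(pf))
    lines <- paste0("@prefix ", names(pf), ": <", pf, "> .")
  tr <- store@triples
  if (nrow(tr)) {
    rdfType <- iri(paste0(RDF_NS, "type"))
    for (s in unique(tr$subject)) {
      rows <- tr[tr$subject == s, , drop = FALSE]
      stext <- if (isTermBlank(s)) s else compactIRI(s, pf)
      ptexts <- character(0)
      for (p in unique(rows$predicate)) {
        objs <- rows$object[rows$predicate == p]
        ptext <- if (p == rdfType) "a" else compactIRI(p, pf)
        otexts <- vapply(objs, serializeTerm, character(1), prefixes = pf)
        ptexts <- c(ptexts, paste(ptext, paste(otexts, collapse = " , ")))
      }
      lines <- c(lines, "", paste0(stext, " ", paste(ptexts, collapse = " ;\n    "), " ."))
    }
  }
  doc <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Read a Turtle/N3 file into a TripleStore
#' @param path file path.
#' @param base base IRI for relative references.
#' @export
readRDF <- function(path, base = "") {
  parseRDF(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n"), base = base)
}
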