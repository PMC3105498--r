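# SPARQL SELECT over the in-memory store.
#
# Supported subset: PREFIX declarations, SELECT with an explicit variable
# list, DISTINCT, basic graph patterns (with ';', ',', and anonymous []
# nodes), FILTER with numeric/string comparisons, regex(), && and ||,
# OPTIONAL blocks, and LIMIT. Anything else fails with an "unsupported
# SPARQL" error rather than a silently wrong answer.

SPARQL_UNSUPPORTED <- c("UNION", "GRAPH", "ORDER", "GROUP", "HAVING", "ASK",
                        "CONSTRUCT", "DESCRIBE", "INSERT", "DELETE", "BIND",
                        "VALUES", "MINUS", "SERVICE", "OFFSET", "REDUCED",
                        "FROM", "EXISTS", "NOT")

unsupportedSparql <- function(what, line = NULL) {
  stop("unsupported SPARQL feature",
       if (!is.null(line)) paste0(" at line ", line), ": ", what,
       call. = FALSE)
}

# Parse a SELECT query into list(variables, distinct, patterns, filters,
# optionals, limit). Patterns are data.frames of term/var columns where
# variables are encoded as "?name".
parseSparql <- function(text) {
  cur <- tokenCursor(rdfTokenize(text, sparql = TRUE))
  prefixes <- list()
  nanon <- 0L

  keyword <- function(tok, word)
    tok$type == "WORD" && toupper(tok$value) == word

  # prologue
  repeat {
    tok <- cur$peek()
    if (keyword(tok, "PREFIX")) {
      cur$next_()
      pn <- cur$expect("PNAME")
      ns <- cur$expect("IRIREF")
      prefixes[[sub(":.*$", "", pn$value)]] <- ns$value
    } else if (keyword(tok, "BASE")) {
      unsupportedSparql("BASE", tok$line)
    } else break
  }

  tok <- cur$peek()
  if (!keyword(tok, "SELECT")) {
    if (tok$type == "WORD" && toupper(tok$value) %in% SPARQL_UNSUPPORTED)
      unsupportedSparql(toupper(tok$value), tok$line)
    stop("parse error at line ", tok$line, ": expected SELECT")
  }
  cur$next_()
  distinct <- FALSE
  if (keyword(cur$peek(), "DISTINCT")) { cur$next_(); distinct <- TRUE }
  if (keyword(cur$peek(), "REDUCED")) unsupportedSparql("REDUCED", cur$peek()$line)
  vars <- character(0)
  repeat {
    tok <- cur$peek()
    if (tok$type == "VAR") { cur$next_(); vars <- c(vars, tok$value) }
    else if (tok$type == "OP" && tok$value == "*")
      unsupportedSparql("SELECT * (explicit projection required)", tok$line)
    else break
  }
  if (!length(vars))
    stop("parse error: SELECT requires at least one projected variable")
  if (anyDuplicated(vars))
    stop("parse error: duplicate variable in SELECT projection")

  if (!keyword(cur$peek(), "WHERE"))
    stop("parse error at line ", cur$peek()$line, ": expected WHERE")
  cur$next_()
  cur$expect("PUNCT", "{")

  parseTermOrVar <- function(allowLiteral = TRUE) {
    tok <- cur$peek()
    if (tok$type == "VAR") { cur$next_(); return(paste0("?", tok$value)) }
    if (tok$type == "IRIREF") { cur$next_(); return(iri(tok$value)) }
    if (tok$type == "PNAME") { cur$next_(); return(iri(expandPName(tok$value, prefixes, tok$line))) }
    if (tok$type == "PUNCT" && tok$value == "[") {
      # anonymous node: a fresh variable that is never projected
      cur$next_()
      nxt <- cur$peek()
      if (!(nxt$type == "PUNCT" && nxt$value == "]"))
        unsupportedSparql("non-empty [] property list in query patterns", nxt$line)
      cur$next_()
      nanon <<- nanon + 1L
      return(paste0("?.anon", nanon))
    }
    if (allowLiteral) {
      if (tok$type == "STRING") {
        cur$next_()
        lex <- unescapeLiteral(tok$value)
        nxt <- cur$peek()
        if (nxt$type == "LANGTAG") { cur$next_(); return(literal(lex, lang = nxt$value)) }
        if (nxt$type == "DTYPE") {
          cur$next_()
          dt <- cur$next_()
          dtIRI <- if (dt$type == "IRIREF") dt$value
                   else expandPName(dt$value, prefixes, dt$line)
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
    if (tok$type == "WORD" && toupper(tok$value) %in% SPARQL_UNSUPPORTED)
      unsupportedSparql(toupper(tok$value), tok$line)
    stop("parse error at line ", tok$line, ": unexpected '", tok$value, "'")
  }

  parseFilterExpr <- function() {
    # expr := conj (|| conj)* ; conj := atom (&& atom)*
    parseAtom <- function() {
      tok <- cur$peek()
      if (tok$type == "PUNCT" && tok$value == "(") {
        cur$next_()
        e <- parseOr()
        cur$expect("PUNCT", ")")
        return(e)
      }
      if (tok$type == "OP" && tok$value == "!") {
        cur$next_()
        return(list(op = "!", e = parseAtom()))
      }
      if (tok$type == "WORD" && tolower(tok$value) == "regex") {
        cur$next_()
        cur$expect("PUNCT", "(")
        v <- parseTermOrVar()
        cur$expect("PUNCT", ",")
        pat <- cur$expect("STRING")
        flags <- ""
        if (cur$peek()$type == "PUNCT" && cur$peek()$value == ",") {
          cur$next_(); flags <- cur$expect("STRING")$value
        }
        cur$expect("PUNCT", ")")
        return(list(op = "regex", e = v, pattern = unescapeLiteral(pat$value),
                    flags = flags))
      }
      if (tok$type == "WORD" &&
          !(tolower(tok$value) %in% c("true", "false")))
        unsupportedSparql(paste0("FILTER function ", tok$value, "()"), tok$line)
      lhs <- parseTermOrVar()
      op <- cur$peek()
      if (!(op$type == "OP" && op$value %in% c("=", "!=", "<", "<=", ">", ">=")))
        stop("parse error at line ", op$line, ": expected comparison operator")
      cur$next_()
      rhs <- parseTermOrVar()
      list(op = op$value, lhs = lhs, rhs = rhs)
    }
    parseAnd <- function() {
      e <- parseAtom()
      while (cur$peek()$type == "OP" && cur$peek()$value == "&&") {
        cur$next_()
        e <- list(op = "&&", a = e, b = parseAtom())
      }
      e
    }
    parseOr <- function() {
      e <- parseAnd()
      while (cur$peek()$type == "OP" && cur$peek()$value == "||") {
        cur$next_()
        e <- list(op = "||", a = e, b = parseAnd())
      }
      e
    }
    parseOr()
  }

  patterns <- list()   # each: c(s, p, o)
  filters <- list()
  optionals <- list()  # each: list of patterns

  parseTriplesBlock <- function(sink) {
    # parses one subject's predicate-object list; returns updated sink
    s <- parseTermOrVar(allowLiteral = FALSE)
    repeat {
      tok <- cur$peek()
      p <- if (tok$type == "WORD" && tok$value == "a") {
        cur$next_(); iri(paste0(RDF_NS, "type"))
      } else parseTermOrVar(allowLiteral = FALSE)
      repeat {
        o <- parseTermOrVar()
        sink[[length(sink) + 1L]] <- c(s, p, o)
        if (cur$peek()$type == "PUNCT" && cur$peek()$value == ",") cur$next_()
        else break
      }
      if (cur$peek()$type == "PUNCT" && cur$peek()$value == ";") {
        cur$next_()
        nxt <- cur$peek()
        if (nxt$type == "PUNCT" && nxt$value %in% c(".", "}")) break
      } else break
    }
    if (cur$peek()$type == "PUNCT" && cur$peek()$value == ".") cur$next_()
    sink
  }

  repeat {
    tok <- cur$peek()
    if (tok$type == "PUNCT" && tok$value == "}") { cur$next_(); break }
    if (keyword(tok, "FILTER")) {
      cur$next_()
      # both FILTER (expr) and FILTER regex(...) forms: the expression
      # grammar itself handles parenthesized expressions
      filters[[length(filters) + 1L]] <- parseFilterExpr()
      next
    }
    if (keyword(tok, "OPTIONAL")) {
      cur$next_()
      cur$expect("PUNCT", "{")
      block <- list()
      repeat {
        t2 <- cur$peek()
        if (t2$type == "PUNCT" && t2$value == "}") { cur$next_(); break }
        if (t2$type == "WORD" && toupper(t2$value) %in%
              c(SPARQL_UNSUPPORTED, "FILTER", "OPTIONAL"))
          unsupportedSparql(paste("nested", toupper(t2$value), "inside OPTIONAL"),
                            t2$line)
        block <- parseTriplesBlock(block)
      }
      optionals[[length(optionals) + 1L]] <- block
      next
    }
    if (tok$type == "WORD" && toupper(tok$value) %in% SPARQL_UNSUPPORTED)
      unsupportedSparql(toupper(tok$value), tok$line)
    if (tok$type == "PUNCT" && tok$value == "{")
      unsupportedSparql("nested graph-pattern groups (UNION/alternatives)",
                        tok$line)
    patterns <- parseTriplesBlock(patterns)
  }

  limit <- NULL
  tok <- cur$peek()
  if (keyword(tok, "LIMIT")) {
    cur$next_()
    limit <- as.integer(cur$expect("NUMBER")$value)
  }
  tok <- cur$peek()
  if (tok$type != "EOF") {
    if (tok$type == "WORD" && toupper(tok$value) %in% SPARQL_UNSUPPORTED)
      unsupportedSparql(toupper(tok$value), tok$line)
    stop("parse error at line ", tok$line, ": trailing input '", tok$value, "'")
  }
  list(variables = vars, distinct = distinct, patterns = patterns,
       filters = filters, optionals = optionals, limit = limit)
}

#' Projected variables of a SPARQL SELECT query
#'
#' @param sparql SELECT query text with an explicit variable list
#'   (\code{SELECT *} is rejected).
#' @return character vector of variable names in projection order.
#' @export
selectVariables <- function(sparql) parseSparql(sparql)$variables

isQueryVar <- function(x) startsWith(x, "?")

# match one triple pattern against the store; returns a bindings data.frame
matchPattern <- function(tr, pat) {
  keep <- rep(TRUE, nrow(tr))
  cols <- list()
  slots <- c("subject", "predicate", "object")
  for (k in 1:3) {
    t <- pat[k]
    if (isQueryVar(t)) cols[[substr(t, 2L, nchar(t))]] <- slots[k]
    else keep <- keep & tr[[slots[k]]] == t
  }
  rows <- tr[keep, , drop = FALSE]
  if (!length(cols))
    return(structure(data.frame(matrix(nrow = nrow(rows), ncol = 0)),
                     names = character(0)))
  out <- data.frame(lapply(cols, function(slot) rows[[slot]]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(cols)
  # a variable repeated within one pattern must bind consistently
  if (anyDuplicated(names(cols))) {
    dup <- unique(names(cols)[duplicated(names(cols))])
    for (v in dup) {
      ix <- which(names(out) == v)
      same <- Reduce(`&`, lapply(ix[-1], function(j) out[[ix[1]]] == out[[j]]))
      out <- out[same, , drop = FALSE]
    }
    out <- out[, !duplicated(names(out)), drop = FALSE]
  }
  unique(out)
}

joinBindings <- function(a, b, left = FALSE) {
  if (is.null(a)) return(b)
  common <- intersect(names(a), names(b))
  if (!length(common)) {
    if (!nrow(a) || !nrow(b)) {
      if (left && nrow(a)) {
        for (v in names(b)) a[[v]] <- NA_character_
        return(a)
      }
      empty <- a[0, , drop = FALSE]
      for (v in setdiff(names(b), names(a))) empty[[v]] <- character(0)
      return(empty)
    }
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    return(cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE]))
  }
  m <- merge(cbind(a, .rowid = seq_len(max(nrow(a), 1L))[seq_len(nrow(a))]),
             b, by = common, all.x = left, sort = FALSE)
  m$.rowid <- NULL
  rownames(m) <- NULL
  m
}

evalFilter <- function(expr, bindings) {
  n <- nrow(bindings)
  valOf <- function(t) {
    if (isQueryVar(t)) {
      v <- substr(t, 2L, nchar(t))
      if (!v %in% names(bindings)) rep(NA_character_, n)
      else bindings[[v]]
    } else rep(t, n)
  }
  ev <- function(e) {
    switch(e$op,
      "&&" = ev(e$a) & ev(e$b),
      "||" = ev(e$a) | ev(e$b),
      "!" = !ev(e$e),
      "regex" = {
        x <- termText(valOf(e$e))
        res <- grepl(e$pattern, x, perl = TRUE,
                     ignore.case = grepl("i", e$flags %||% "", fixed = TRUE))
        res & !is.na(x)
      },
      {
        lhs <- valOf(e$lhs); rhs <- valOf(e$rhs)
        ln <- termNumeric(lhs); rn <- termNumeric(rhs)
        numeric <- !is.na(ln) & !is.na(rn)
        lt <- termText(lhs); rt <- termText(rhs)
        res <- switch(e$op,
          "=" = ifelse(numeric, ln == rn, lt == rt),
          "!=" = ifelse(numeric, ln != rn, lt != rt),
          "<" = ifelse(numeric, ln < rn, lt < rt),
          "<=" = ifelse(numeric, ln <= rn, lt <= rt),
          ">" = ifelse(numeric, ln > rn, lt > rt),
          ">=" = ifelse(numeric, ln >= rn, lt >= rt))
        res & !is.na(lhs) & !is.na(rhs)
      })
  }
  out <- ev(expr)
  out & !is.na(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a SPARQL SELECT query against a TripleStore
#'
#' Evaluates the supported subset (basic graph patterns, DISTINCT, FILTER
#' with comparisons and regex, OPTIONAL, LIMIT). Unsupported constructs
#' raise an error; they are never silently ignored.
#'
#' @param store a \code{TripleStore}.
#' @param sparql SELECT query text.
#' @return a \code{\link{ResultTable}}.
#' @examples
#' st <- tripleStore(iri("http://e.org/s"), iri("http://e.org/p"), literal("v"))
#' q <- "SELECT ?p WHERE { ?s ?p ?o }"
#' resultCount(query(st, q))
#' @export
query <- function(store, sparql) {
  q <- parseSparql(sparql)
  tr <- store@triples
  bindings <- NULL
  for (pat in q$patterns)
    bindings <- joinBindings(bindings, matchPattern(tr, pat))
  if (is.null(bindings))
    bindings <- structure(data.frame(matrix(nrow = 1L, ncol = 0)),
                          names = character(0))
  for (block in q$optionals) {
    opt <- NULL
    for (pat in block) opt <- joinBindings(opt, matchPattern(tr, pat))
    if (!is.null(opt)) bindings <- joinBindings(bindings, opt, left = TRUE)
  }
  for (f in q$filters)
    bindings <- bindings[evalFilter(f, bindings), , drop = FALSE]
  out <- data.frame(matrix(NA_character_, nrow = nrow(bindings),
                           ncol = length(q$variables)),
                    stringsAsFactors = FALSE)
  names(out) <- q$variables
  for (v in q$variables)
    if (v %in% names(bindings)) out[[v]] <- bindings[[v]]
  if (q$distinct) out <- unique(out)
  if (!is.null(q$limit)) out <- utils::head(out, q$limit)
  rownames(out) <- NULL
  resultTable(q$variables, out)
}
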