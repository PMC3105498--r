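# Chemical graphs to and from RDF, following the CDK-data-model vocabulary
# (Molecule/Atom/Bond classes; hasAtom, hasBond, symbol, order properties;
# Dublin Core title; owl:sameAs identity links to the InChI resolver).
# Atom and bond indices are serialized explicitly (cdk:index) because RDF
# asserts no statement order, and round-trips must be order-deterministic.

DEFAULT_RESOLVER <- "http://rdf.openmolecules.net/"

#' Map an InChI to its resolver URI and back
#'
#' The identity convention appends the InChI body (percent-encoded where
#' needed) as the query string of the resolver base, e.g.
#' \code{http://rdf.openmolecules.net/?InChI=1/CH4/h1H4}.
#'
#' @param inchi InChI string starting with \code{InChI=}.
#' @param uri resolver URI produced by \code{inchiToURI}.
#' @param base resolver base IRI (trailing slash included).
#' @return \code{inchiToURI}: the URI; \code{uriToInchi}: the InChI. The
#'   two functions are mutual inverses.
#' @examples
#' inchiToURI("InChI=1/CH4/h1H4")
#' @export
inchiToURI <- function(inchi, base = DEFAULT_RESOLVER) {
  stopifnot(is.character(inchi))
  if (!all(startsWith(inchi, "InChI=")))
    stop("not an InChI (must start with 'InChI=')")
  body <- substr(inchi, 7L, nchar(inchi))
  enc <- vapply(body, function(b) utils::URLencode(b, reserved = FALSE),
                character(1), USE.NAMES = FALSE)
  paste0(base, "?InChI=", enc)
}

#' @rdname inchiToURI
#' @export
uriToInchi <- function(uri, base = DEFAULT_RESOLVER) {
  stopifnot(is.character(uri))
  prefix <- paste0(base, "?InChI=")
  if (!all(startsWith(uri, prefix)))
    stop("not a resolver URI (must start with '", prefix, "')")
  body <- substr(uri, nchar(prefix) + 1L, nchar(uri))
  paste0("InChI=", vapply(body, utils::URLdecode, character(1),
                          USE.NAMES = FALSE))
}

#' Serialize a Molecule to RDF
#'
#' Emits one molecule resource (typed \code{cdk:Molecule}), one resource
#' per atom (element symbol, explicit index, implicit hydrogen count,
#' charge when nonzero, aromatic flag when set) and one per bond (links to
#' both atoms, order, index). The name is attached with \code{dc:title},
#' the SMILES with \code{cdk:smiles}, and an InChI annotation becomes an
#' \code{owl:sameAs} link to the resolver URI.
#'
#' @param mol a \code{Molecule}.
#' @param base IRI under which the molecule/atom/bond resources are minted.
#' @param resolver InChI resolver base for identity links.
#' @return a \code{TripleStore}.
#' @export
moleculeToRDF <- function(mol, base = "http://example.com/mol1",
                          resolver = DEFAULT_RESOLVER) {
  base <- sub("/+$", "", base)
  molIRI <- iri(base)
  s <- character(0); p <- character(0); o <- character(0)
  say <- function(su, pr, ob) {
    s[length(s) + 1L] <<- su; p[length(p) + 1L] <<- pr; o[length(o) + 1L] <<- ob
  }
  say(molIRI, rdfTypeIRI(), cdkIRI("Molecule"))
  if (!is.na(mol@name)) say(molIRI, dcTitleIRI(), literal(mol@name))
  if (!is.na(mol@smiles)) say(molIRI, cdkIRI("smiles"), literal(mol@smiles))
  if (!is.na(mol@inchi))
    say(molIRI, owlSameAsIRI(), iri(inchiToURI(mol@inchi, resolver)))
  a <- mol@atoms
  atomIRI <- function(k) iri(paste0(base, "/atom", k))
  for (k in seq_len(nrow(a))) {
    ai <- atomIRI(k)
    say(molIRI, cdkIRI("hasAtom"), ai)
    say(ai, rdfTypeIRI(), cdkIRI("Atom"))
    say(ai, cdkIRI("symbol"), literal(a$element[k]))
    say(ai, cdkIRI("index"), literal(as.integer(k)))
    say(ai, cdkIRI("implicitHydrogenCount"), literal(as.integer(a$implicitH[k])))
    if (a$charge[k] != 0L)
      say(ai, cdkIRI("formalCharge"), literal(as.integer(a$charge[k])))
    if (a$aromatic[k]) say(ai, cdkIRI("aromatic"), literal(TRUE))
  }
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    bi <- iri(paste0(base, "/bond", k))
    say(molIRI, cdkIRI("hasBond"), bi)
    say(bi, rdfTypeIRI(), cdkIRI("Bond"))
    say(bi, cdkIRI("bindsAtom"), atomIRI(b$atom1[k]))
    say(bi, cdkIRI("bindsAtom"), atomIRI(b$atom2[k]))
    say(bi, cdkIRI("order"), literal(b$order[k]))
    say(bi, cdkIRI("index"), literal(as.integer(k)))
  }
  tripleStore(s, p, o, prefixes = chemrdfPrefixes())
}

storeObjects <- function(store, subject, predicate) {
  tr <- store@triples
  tr$object[tr$subject == subject & tr$predicate == predicate]
}

#' Reconstruct a Molecule from its RDF serialization
#'
#' @param store a \code{TripleStore} holding a CDK-model molecule graph.
#' @param moleculeIRI IRI text of the molecule resource; when NULL the
#'   single \code{cdk:Molecule}-typed resource in the store is used.
#' @param resolver InChI resolver base for reading identity links back.
#' @return a \code{Molecule} with atoms ordered by their serialized index.
#' @export
moleculeFromRDF <- function(store, moleculeIRI = NULL,
                            resolver = DEFAULT_RESOLVER) {
  tr <- store@triples
  typed <- tr$subject[tr$predicate == rdfTypeIRI() &
                        tr$object == cdkIRI("Molecule")]
  if (is.null(moleculeIRI)) {
    if (!length(typed)) stop("no cdk:Molecule resource found in store")
    if (length(typed) > 1L)
      stop("store holds ", length(typed), " molecules; pass moleculeIRI")
    molIRI <- typed[1]
  } else {
    molIRI <- iri(moleculeIRI)
    if (!molIRI %in% typed)
      stop("no cdk:Molecule resource found at <", moleculeIRI, ">")
  }
  lit1 <- function(subj, prop, required = FALSE) {
    v <- storeObjects(store, subj, cdkIRI(prop))
    if (!length(v)) {
      if (required) stop("molecule RDF is missing cdk:", prop, " on ", subj)
      return(NA_character_)
    }
    literalValue(v[1])
  }
  atomIRIs <- storeObjects(store, molIRI, cdkIRI("hasAtom"))
  idx <- vapply(atomIRIs, function(ai) as.integer(lit1(ai, "index", TRUE)),
                integer(1))
  atomIRIs <- atomIRIs[order(idx)]
  el <- vapply(atomIRIs, function(ai) lit1(ai, "symbol", TRUE), character(1))
  if (!all(el %in% SUPPORTED_ELEMENTS))
    stop("unknown element in molecule RDF: ",
         paste(setdiff(el, SUPPORTED_ELEMENTS), collapse = ", "))
  impH <- vapply(atomIRIs, function(ai) {
    v <- lit1(ai, "implicitHydrogenCount")
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  charge <- vapply(atomIRIs, function(ai) {
    v <- lit1(ai, "formalCharge")
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  arom <- vapply(atomIRIs, function(ai) {
    v <- lit1(ai, "aromatic")
    !is.na(v) && v == "true"
  }, logical(1))

  bondIRIs <- storeObjects(store, molIRI, cdkIRI("hasBond"))
  bidx <- vapply(bondIRIs, function(bi) as.integer(lit1(bi, "index", TRUE)),
                 integer(1))
  bondIRIs <- bondIRIs[order(bidx)]
  a1 <- integer(0); a2 <- integer(0); ord <- character(0)
  for (bi in bondIRIs) {
    ends <- storeObjects(store, bi, cdkIRI("bindsAtom"))
    pos <- match(ends, atomIRIs)
    if (length(pos) != 2L || any(is.na(pos)))
      stop("bond ", bi, " is missing an atom endpoint")
    a1 <- c(a1, min(pos)); a2 <- c(a2, max(pos))
    ord <- c(ord, lit1(bi, "order", TRUE))
  }
  nm <- storeObjects(store, molIRI, dcTitleIRI())
  smi <- storeObjects(store, molIRI, cdkIRI("smiles"))
  same <- storeObjects(store, molIRI, owlSameAsIRI())
  inchi <- NA_character_
  for (u in same) {
    v <- tryCatch(uriToInchi(iriValue(u), resolver), error = function(e) NULL)
    if (!is.null(v)) { inchi <- v; break }
  }
  molecule(
    atoms = data.frame(element = unname(el), charge = charge,
                       implicitH = impH, aromatic = arom,
                       stringsAsFactors = FALSE),
    bonds = data.frame(atom1 = a1, atom2 = a2, order = ord,
                       stringsAsFactors = FALSE),
    name = if (length(nm)) literalValue(nm[1]) else NA_character_,
    smiles = if (length(smi)) literalValue(smi[1]) else NA_character_,
    inchi = inchi)
}

# --- formula and weight ----------------------------------------------------

ATOMIC_WEIGHTS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                    Br = 79.904, I = 126.904)

elementCounts <- function(mol) {
  a <- mol@atoms
  counts <- table(a$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  nH <- sum(a$implicitH) + if ("H" %in% names(counts)) counts[["H"]] else 0L
  counts <- counts[names(counts) != "H"]
  if (nH > 0L) counts <- c(counts, H = as.integer(nH))
  counts
}

#' Molecular formula in Hill order
#'
#' Carbon first, hydrogen second, all other elements alphabetically (all
#' elements alphabetically when no carbon is present). Implicit hydrogens
#' are included.
#' @param mol a \code{Molecule}.
#' @return formula string, "" for an empty molecule.
#' @export
molecularFormula <- function(mol) {
  counts <- elementCounts(mol)
  if (!length(counts)) return("")
  els <- names(counts)
  ordered <- if ("C" %in% els)
    c("C", intersect("H", els), sort(setdiff(els, c("C", "H"))))
  else sort(els)
  paste(vapply(ordered, function(e)
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""), character(1)),
    collapse = "")
}

#' Molecular weight in Dalton
#'
#' Sum of standard atomic weights over all atoms including implicit
#' hydrogens.
#' @param mol a \code{Molecule}.
#' @export
molecularWeight <- function(mol) {
  counts <- elementCounts(mol)
  if (!length(counts)) return(0)
  sum(ATOMIC_WEIGHTS[names(counts)] * counts)
}
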