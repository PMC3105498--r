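#' @import methods
NULL

#' In-memory RDF triple store
#'
#' Holds a duplicate-free set of subject--predicate--object triples in the
#' canonical term encoding (see \code{\link{iri}}, \code{\link{literal}})
#' plus a prefix map used when serializing.
#'
#' @slot triples data.frame with character columns \code{subject},
#'   \code{predicate}, \code{object}.
#' @slot prefixes named character vector mapping prefix to namespace IRI.
#' @export
setClass("TripleStore",
  representation(triples = "data.frame", prefixes = "character"),
  prototype(triples = data.frame(subject = character(0),
                                 predicate = character(0),
                                 object = character(0),
                                 stringsAsFactors = FALSE),
            prefixes = character(0)))

setValidity("TripleStore", function(object) {
  tr <- object@triples
  if (!all(c("subject", "predicate", "object") %in% names(tr)))
    return("triples must have subject, predicate, object columns")
  if (nrow(tr)) {
    if (!all(isTermIRI(tr$predicate)))
      return("every predicate must be an IRI")
    if (!all(isTermIRI(tr$subject) | isTermBlank(tr$subject)))
      return("subjects must be IRIs or blank nodes")
    key <- paste(tr$subject, tr$predicate, tr$object, sep = "\r")
    if (anyDuplicated(key)) return("duplicate triples are not allowed")
  }
  if (length(object@prefixes)) {
    if (is.null(names(object@prefixes)) || any(names(object@prefixes) == ""))
      return("prefixes must be named")
    if (!all(grepl("^[A-Za-z][A-Za-z0-9+.-]*:", object@prefixes)))
      return("every prefix must map to an absolute IRI")
  }
  TRUE
})

#' Construct a TripleStore
#'
#' @param subject,predicate,object character vectors of canonical terms
#'   (recycled to common length); may all be omitted for an empty store.
#' @param prefixes named character vector of prefix -> namespace IRI.
#' @return a \code{TripleStore}.
#' @examples
#' st <- tripleStore(iri("http://example.org/a"),
#'                   iri("http://example.org/p"), literal("v"))
#' tripleCount(st)
#' @export
tripleStore <- function(subject = character(0), predicate = character(0),
                        object = character(0), prefixes = character(0)) {
  n <- max(length(subject), length(predicate), length(object))
  tr <- data.frame(subject = rep_len(subject, n),
                   predicate = rep_len(predicate, n),
                   object = rep_len(object, n), stringsAsFactors = FALSE)
  key <- paste(tr$subject, tr$predicate, tr$object, sep = "\r")
  tr <- tr[!duplicated(key), , drop = FALSE]
  rownames(tr) <- NULL
  new("TripleStore", triples = tr, prefixes = prefixes)
}

#' @describeIn tripleStore add triples (duplicates silently dropped).
#' @param store a \code{TripleStore}.
#' @export
addTriples <- function(store, subject, predicate, object) {
  tr <- rbind(store@triples,
              data.frame(subject = subject, predicate = predicate,
                         object = object, stringsAsFactors = FALSE))
  key <- paste(tr$subject, tr$predicate, tr$object, sep = "\r")
  tr <- tr[!duplicated(key), , drop = FALSE]
  rownames(tr) <- NULL
  initialize(store, triples = tr)
}

#' @describeIn tripleStore number of triples held.
#' @export
tripleCount <- function(store) nrow(store@triples)

#' @describeIn tripleStore the triples as a data.frame of canonical terms.
#' @export
triples <- function(store) store@triples

#' @describeIn tripleStore the prefix map.
#' @export
storePrefixes <- function(store) store@prefixes

#' @describeIn tripleStore merge prefix declarations into the store.
#' @param new named character vector of prefixes to add.
#' @export
withPrefixes <- function(store, new) {
  pf <- store@prefixes
  pf[names(new)] <- new
  initialize(store, prefixes = pf)
}

setMethod("show", "TripleStore", function(object) {
  cat("TripleStore with", nrow(object@triples), "triples and",
      length(object@prefixes), "prefixes\n")
  if (nrow(object@triples)) {
    head <- utils::head(object@triples, 5L)
    for (i in seq_len(nrow(head)))
      cat(" ", head$subject[i], head$predicate[i], head$object[i], ".\n")
    if (nrow(object@triples) > 5L) cat("  ...\n")
  }
})

#' SPARQL SELECT result table
#'
#' @slot variables projected variable names, in projection order.
#' @slot bindings data.frame of canonical terms, one column per variable,
#'   \code{NA} for unbound cells.
#' @export
setClass("ResultTable",
  representation(variables = "character", bindings = "data.frame"))

setValidity("ResultTable", function(object) {
  if (!identical(names(object@bindings), object@variables))
    return("binding columns must match declared variables")
  TRUE
})

resultTable <- function(variables, bindings) {
  new("ResultTable", variables = variables, bindings = bindings)
}

#' @describeIn resultVariables number of solution rows.
#' @export
resultCount <- function(result) nrow(result@bindings)

#' Accessors for ResultTable
#' @param result a \code{ResultTable}.
#' @return \code{resultVariables}: the projected variable names.
#' @export
resultVariables <- function(result) result@variables

#' @describeIn resultVariables the raw bindings (canonical terms).
#' @export
resultBindings <- function(result) result@bindings

#' @export
#' @describeIn resultVariables plain-text view (IRIs unbracketed, literal
#'   lexical values, empty string for unbound) suitable for CSV export.
setMethod("as.data.frame", "ResultTable", function(x, ...) {
  out <- as.data.frame(lapply(x@bindings, termText),
                       stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- x@variables
  out
})

setMethod("show", "ResultTable", function(object) {
  cat("ResultTable:", nrow(object@bindings), "rows,",
      length(object@variables), "variables (",
      paste(object@variables, collapse = ", "), ")\n")
})

#' Write a ResultTable as CSV (one column per variable, empty cell when
#' unbound)
#' @param result a \code{ResultTable}.
#' @param path output file path.
#' @export
writeResultCSV <- function(result, path) {
  df <- as.data.frame(result)
  df[is.na(df)] <- ""
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Chemical graph with implicit hydrogens
#'
#' Atoms carry an element symbol, formal charge, an implicit hydrogen count
#' filled in at parse time from standard valences, and an aromatic flag.
#' Bonds join two distinct atom indices with an order in
#' single/double/triple/aromatic. The graph may be disconnected.
#'
#' @slot atoms data.frame: element, charge, implicitH, aromatic.
#' @slot bonds data.frame: atom1, atom2, order.
#' @slot name,smiles,inchi optional annotation strings (NA when absent).
#' @export
setClass("Molecule",
  representation(atoms = "data.frame", bonds = "data.frame",
                 name = "character", smiles = "character",
                 inchi = "character"),
  prototype(atoms = data.frame(element = character(0), charge = integer(0),
                               implicitH = integer(0), aromatic = logical(0),
                               stringsAsFactors = FALSE),
            bonds = data.frame(atom1 = integer(0), atom2 = integer(0),
                               order = character(0), stringsAsFactors = FALSE),
            name = NA_character_, smiles = NA_character_,
            inchi = NA_character_))

SUPPORTED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  if (!all(a$element %in% SUPPORTED_ELEMENTS))
    return(paste("unsupported element:",
                 paste(setdiff(a$element, SUPPORTED_ELEMENTS), collapse = ",")))
  if (nrow(a) && any(a$implicitH < 0)) return("negative implicit H count")
  if (nrow(b)) {
    if (!all(b$order %in% BOND_ORDERS)) return("invalid bond order")
    if (any(b$atom1 == b$atom2)) return("bond endpoints must differ")
    if (any(b$atom1 < 1 | b$atom1 > nrow(a) | b$atom2 < 1 | b$atom2 > nrow(a)))
      return("bond endpoint out of range")
    key <- paste(pmin(b$atom1, b$atom2), pmax(b$atom1, b$atom2))
    if (anyDuplicated(key)) return("duplicate bond between the same atom pair")
  }
  TRUE
})

#' Construct a Molecule from atom and bond tables
#'
#' @param atoms data.frame with columns element (symbol), charge (integer),
#'   implicitH (integer), aromatic (logical); missing columns get defaults.
#' @param bonds data.frame with columns atom1, atom2 (1-based indices) and
#'   order (one of single/double/triple/aromatic).
#' @param name,smiles,inchi optional annotations.
#' @export
molecule <- function(atoms = NULL, bonds = NULL, name = NA_character_,
                     smiles = NA_character_, inchi = NA_character_) {
  if (is.null(atoms))
    atoms <- data.frame(element = character(0), stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- integer(nrow(atoms))
  if (is.null(atoms$implicitH)) atoms$implicitH <- integer(nrow(atoms))
  if (is.null(atoms$aromatic)) atoms$aromatic <- logical(nrow(atoms))
  atoms <- atoms[, c("element", "charge", "implicitH", "aromatic")]
  atoms$charge <- as.integer(atoms$charge)
  atoms$implicitH <- as.integer(atoms$implicitH)
  if (is.null(bonds))
    bonds <- data.frame(atom1 = integer(0), atom2 = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
  bonds <- bonds[, c("atom1", "atom2", "order")]
  bonds$atom1 <- as.integer(bonds$atom1); bonds$atom2 <- as.integer(bonds$atom2)
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new("Molecule", atoms = atoms, bonds = bonds, name = name,
      smiles = smiles, inchi = inchi)
}

#' @describeIn molecule atom table accessor.
#' @param mol a \code{Molecule}.
#' @export
atoms <- function(mol) mol@atoms

#' @describeIn molecule bond table accessor.
#' @export
bonds <- function(mol) mol@bonds

#' @describeIn molecule number of (heavy, explicit) atoms.
#' @export
atomCount <- function(mol) nrow(mol@atoms)

#' @describeIn molecule number of bonds.
#' @export
bondCount <- function(mol) nrow(mol@bonds)

#' @describeIn molecule molecule display name (NA when unset).
#' @export
moleculeName <- function(mol) mol@name

setMethod("show", "Molecule", function(object) {
  cat("Molecule", if (!is.na(object@name)) paste0("'", object@name, "'") else "",
      ":", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds")
  fm <- tryCatch(molecularFormula(object), error = function(e) NA)
  if (!is.na(fm) && nzchar(fm)) cat(" (", fm, ")", sep = "")
  cat("\n")
})

#' Structural equality of two molecules (same atom order)
#'
#' Compares element, charge, implicit hydrogens, aromatic flags, the bond
#' list with orders (endpoint order ignored), and the name annotation.
#' @param a,b \code{Molecule} objects.
#' @export
sameStructure <- function(a, b) {
  if (nrow(a@atoms) != nrow(b@atoms) || nrow(a@bonds) != nrow(b@bonds))
    return(FALSE)
  if (!identical(a@atoms$element, b@atoms$element)) return(FALSE)
  if (!identical(a@atoms$charge, b@atoms$charge)) return(FALSE)
  if (!identical(a@atoms$implicitH, b@atoms$implicitH)) return(FALSE)
  if (!identical(a@atoms$aromatic, b@atoms$aromatic)) return(FALSE)
  canon <- function(b_) {
    if (!nrow(b_)) return(character(0))
    sort(paste(pmin(b_$atom1, b_$atom2), pmax(b_$atom1, b_$atom2), b_$order))
  }
  if (!identical(canon(a@bonds), canon(b@bonds))) return(FALSE)
  identical(is.na(a@name), is.na(b@name)) &&
    (is.na(a@name) || identical(a@name, b@name))
}

#' Molecular descriptor result with provenance
#'
#' @slot moleculeRef IRI (or index rendered as text) of the molecule.
#' @slot id descriptor id in the registry.
#' @slot dictionaryEntry IRI of the descriptor dictionary entry.
#' @slot parameterValues named list of parameter values as used.
#' @slot value numeric scalar (or fixed-length vector) result.
#' @slot software c(title, version) provenance.
#' @export
setClass("DescriptorResult",
  representation(moleculeRef = "character", id = "character",
                 dictionaryEntry = "character", parameterValues = "list",
                 value = "numeric", software = "character"))

setMethod("show", "DescriptorResult", function(object) {
  cat("DescriptorResult", object@id, "=",
      paste(format(object@value), collapse = ", "), "\n")
  if (length(object@parameterValues))
    cat("  parameters:",
        paste(names(object@parameterValues), "=",
              unlist(lapply(object@parameterValues, as.character)),
              collapse = "; "), "\n")
  cat("  software:", paste(object@software, collapse = " "), "\n")
})

#' @describeIn descriptorRegistry numeric value of a DescriptorResult.
#' @param result a \code{DescriptorResult}.
#' @export
descriptorValue <- function(result) result@value

#' An NMR spectrum: a set of chemical-shift peaks tied to a molecule
#'
#' @slot id spectrum IRI.
#' @slot moleculeRef IRI of the measured molecule.
#' @slot peaks data.frame with numeric columns shift (ppm) and intensity
#'   (NA when unknown), kept sorted by shift.
#' @slot nucleus nucleus tag, e.g. "13C".
#' @export
setClass("Spectrum",
  representation(id = "character", moleculeRef = "character",
                 peaks = "data.frame", nucleus = "character"))

setValidity("Spectrum", function(object) {
  p <- object@peaks
  if (!all(c("shift", "intensity") %in% names(p)))
    return("peaks need shift and intensity columns")
  if (nrow(p) && any(!is.finite(p$shift))) return("peak shifts must be finite")
  if (nrow(p) && is.unsorted(p$shift)) return("peaks must be sorted by shift")
  TRUE
})

#' Construct a Spectrum
#' @param id spectrum IRI text.
#' @param moleculeRef molecule IRI text.
#' @param shifts numeric chemical shifts in ppm.
#' @param intensities optional nonnegative intensities.
#' @param nucleus nucleus tag (default 13C).
#' @export
spectrum13C <- function(id, moleculeRef, shifts, intensities = NULL,
                        nucleus = "13C") {
  if (is.null(intensities)) intensities <- rep(NA_real_, length(shifts))
  o <- order(shifts)
  new("Spectrum", id = id, moleculeRef = moleculeRef,
      peaks = data.frame(shift = shifts[o], intensity = intensities[o]),
      nucleus = nucleus)
}

#' @describeIn spectrum13C peak table accessor.
#' @param s a \code{Spectrum}.
#' @export
peaks <- function(s) s@peaks

#' @describeIn spectrum13C number of peaks.
#' @export
peakCount <- function(s) nrow(s@peaks)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", object@id, "(", object@nucleus, "),",
      nrow(object@peaks), "peaks:",
      paste(format(object@peaks$shift), collapse = ", "), "ppm\n")
})
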