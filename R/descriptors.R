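# Molecular descriptor registry. Every calculation returns a
# DescriptorResult carrying the parameter values actually used and software
# provenance, so that the result can be serialized to RDF after the Blue
# Obelisk Descriptor Ontology pattern and audited later.

descriptorDictionaryIRI <- function(id) paste0(BODO_NS, id)

chemrdfVersion <- function()
  tryCatch(as.character(utils::packageVersion("chemrdf")),
           error = function(e) "0.0.0")

# registry: id -> list(parameters = list(name = default), fun)
descriptorRegistryEnv <- new.env(parent = emptyenv())

registerDescriptor <- function(id, parameters, fun) {
  assign(id, list(id = id, parameters = parameters, fun = fun,
                  dictionaryEntry = descriptorDictionaryIRI(id)),
         envir = descriptorRegistryEnv)
}

#' The descriptor registry
#'
#' @return data.frame of descriptor ids, their dictionary-entry IRIs and
#'   parameter names.
#' @export
descriptorRegistry <- function() {
  ids <- sort(ls(descriptorRegistryEnv))
  data.frame(
    id = ids,
    dictionaryEntry = vapply(ids, descriptorDictionaryIRI, character(1)),
    parameters = vapply(ids, function(i)
      paste(names(get(i, envir = descriptorRegistryEnv)$parameters),
            collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

connectedComponents <- function(mol) {
  n <- nrow(mol@atoms)
  if (!n) return(0L)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    ra <- find(b$atom1[k]); rb <- find(b$atom2[k])
    if (ra != rb) comp[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @describeIn calcDescriptor cyclomatic ring count:
#'   bonds - atoms + connected components.
#' @export
ringCount <- function(mol)
  nrow(mol@bonds) - nrow(mol@atoms) + connectedComponents(mol)

# --- TPSA ------------------------------------------------------------------

# Fragment surface contributions (A^2) for nitrogen and oxygen
# environments, keyed by element / aromatic / charge / hydrogen count /
# single / double / triple / aromatic bond counts / 3-ring membership.
# Environments outside this table raise an error instead of silently
# contributing zero; atoms other than N and O contribute nothing.
TPSA_TABLE <- local({
  row <- function(el, ar, chg, nH, ns, nd, nt, nar, ring3, contrib)
    data.frame(el = el, ar = ar, chg = chg, nH = nH, ns = ns, nd = nd,
               nt = nt, nar = nar, ring3 = ring3, contrib = contrib,
               stringsAsFactors = FALSE)
  rbind(
    row("N", FALSE, 0L, 0L, 3L, 0L, 0L, 0L, FALSE, 3.24),
    row("N", FALSE, 0L, 0L, 1L, 1L, 0L, 0L, FALSE, 12.36),
    row("N", FALSE, 0L, 0L, 0L, 0L, 1L, 0L, FALSE, 23.79),
    row("N", FALSE, 0L, 0L, 1L, 2L, 0L, 0L, FALSE, 11.68),
    row("N", FALSE, 0L, 0L, 0L, 1L, 1L, 0L, FALSE, 13.60),
    row("N", FALSE, 0L, 0L, 3L, 0L, 0L, 0L, TRUE, 3.01),
    row("N", FALSE, 0L, 1L, 2L, 0L, 0L, 0L, FALSE, 12.03),
    row("N", FALSE, 0L, 1L, 2L, 0L, 0L, 0L, TRUE, 21.94),
    row("N", FALSE, 0L, 1L, 0L, 1L, 0L, 0L, FALSE, 23.85),
    row("N", FALSE, 0L, 2L, 1L, 0L, 0L, 0L, FALSE, 26.02),
    row("N", FALSE, 1L, 0L, 4L, 0L, 0L, 0L, FALSE, 0.00),
    row("N", FALSE, 1L, 0L, 2L, 1L, 0L, 0L, FALSE, 3.01),
    row("N", FALSE, 1L, 0L, 1L, 0L, 1L, 0L, FALSE, 4.36),
    row("N", FALSE, 1L, 1L, 3L, 0L, 0L, 0L, FALSE, 4.44),
    row("N", FALSE, 1L, 1L, 1L, 1L, 0L, 0L, FALSE, 13.97),
    row("N", FALSE, 1L, 2L, 2L, 0L, 0L, 0L, FALSE, 16.61),
    row("N", FALSE, 1L, 3L, 1L, 0L, 0L, 0L, FALSE, 27.64),
    row("N", TRUE, 0L, 0L, 0L, 0L, 0L, 2L, FALSE, 12.89),
    row("N", TRUE, 0L, 0L, 0L, 0L, 0L, 3L, FALSE, 4.41),
    row("N", TRUE, 0L, 0L, 1L, 0L, 0L, 2L, FALSE, 4.93),
    row("N", TRUE, 0L, 0L, 0L, 1L, 0L, 2L, FALSE, 8.39),
    row("N", TRUE, 0L, 1L, 0L, 0L, 0L, 2L, FALSE, 15.79),
    row("N", TRUE, 1L, 0L, 0L, 0L, 0L, 3L, FALSE, 4.10),
    row("N", TRUE, 1L, 0L, 1L, 0L, 0L, 2L, FALSE, 3.88),
    row("N", TRUE, 1L, 1L, 0L, 0L, 0L, 2L, FALSE, 14.14),
    row("O", FALSE, 0L, 0L, 2L, 0L, 0L, 0L, FALSE, 9.23),
    row("O", FALSE, 0L, 0L, 2L, 0L, 0L, 0L, TRUE, 12.53),
    row("O", FALSE, 0L, 0L, 0L, 1L, 0L, 0L, FALSE, 17.07),
    row("O", FALSE, 0L, 1L, 1L, 0L, 0L, 0L, FALSE, 20.23),
    row("O", FALSE, -1L, 0L, 1L, 0L, 0L, 0L, FALSE, 23.06),
    row("O", TRUE, 0L, 0L, 0L, 0L, 0L, 2L, FALSE, 13.14))
})

atomRings3 <- function(mol) {
  # membership in any 3-membered ring, from the bond list directly
  b <- mol@bonds
  n <- nrow(mol@atoms)
  inRing3 <- logical(n)
  if (nrow(b) < 3L) return(inRing3)
  adj <- lapply(seq_len(n), function(a)
    c(b$atom2[b$atom1 == a], b$atom1[b$atom2 == a]))
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (length(nb) >= 2L)
      for (x in nb) if (any(adj[[x]] %in% setdiff(nb, x))) {
        inRing3[a] <- TRUE; break
      }
  }
  inRing3
}

atomInCycle <- function(mol) {
  # atoms lying on at least one cycle: iteratively prune degree-<2 vertices
  n <- nrow(mol@atoms)
  b <- mol@bonds
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    keep <- alive[b$atom1] & alive[b$atom2]
    for (k in which(keep)) {
      deg[b$atom1[k]] <- deg[b$atom1[k]] + 1L
      deg[b$atom2[k]] <- deg[b$atom2[k]] + 1L
    }
    drop <- alive & deg < 2L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  alive
}

tpsaDescriptor <- function(mol, checkAromaticity = FALSE) {
  a <- mol@atoms
  b <- mol@bonds
  if (isTRUE(checkAromaticity)) {
    # re-derive aromaticity from ring membership: a lowercase-marked atom
    # that does not lie on any cycle is an annotation error
    cyc <- atomInCycle(mol)
    bad <- which(a$aromatic & !cyc)
    if (length(bad))
      stop("aromaticity check failed: atom ", bad[1],
           " is marked aromatic but lies on no ring")
  }
  ring3 <- atomRings3(mol)
  total <- 0
  for (k in seq_len(nrow(a))) {
    if (!a$element[k] %in% c("N", "O")) next
    mine <- b$atom1 == k | b$atom2 == k
    other <- ifelse(b$atom1[mine] == k, b$atom2[mine], b$atom1[mine])
    ords <- b$order[mine]
    hNbr <- sum(a$element[other] == "H")
    heavy <- a$element[other] != "H"
    nH <- a$implicitH[k] + hNbr
    ns <- sum(ords[heavy] == "single")
    key <- TPSA_TABLE$el == a$element[k] &
      TPSA_TABLE$ar == a$aromatic[k] &
      TPSA_TABLE$chg == a$charge[k] &
      TPSA_TABLE$nH == nH &
      TPSA_TABLE$ns == ns &
      TPSA_TABLE$nd == sum(ords[heavy] == "double") &
      TPSA_TABLE$nt == sum(ords[heavy] == "triple") &
      TPSA_TABLE$nar == sum(ords[heavy] == "aromatic") &
      TPSA_TABLE$ring3 == ring3[k]
    if (!any(key))
      stop("TPSA contribution unavailable for ", a$element[k], " atom ", k,
           " (charge ", a$charge[k], ", ", nH, " H, bonds: ",
           paste(ords, collapse = ","), ")")
    total <- total + TPSA_TABLE$contrib[which(key)[1]]
  }
  total
}

local({
  registerDescriptor("heavyAtomCount", list(), function(mol, params)
    sum(mol@atoms$element != "H"))
  registerDescriptor("bondCount", list(), function(mol, params)
    nrow(mol@bonds))
  registerDescriptor("ringCount", list(), function(mol, params)
    ringCount(mol))
  registerDescriptor("molecularWeight", list(), function(mol, params)
    molecularWeight(mol))
  registerDescriptor("tpsa", list(checkAromaticity = FALSE),
    function(mol, params) tpsaDescriptor(mol, params$checkAromaticity))
})

#' Calculate a molecular descriptor with provenance
#'
#' @param mol a \code{Molecule}.
#' @param id descriptor id; one of the registry ids listed by
#'   \code{\link{descriptorRegistry}} (heavyAtomCount, bondCount,
#'   ringCount, molecularWeight, tpsa).
#' @param params named list of parameter overrides (e.g.
#'   \code{list(checkAromaticity = TRUE)} for tpsa).
#' @param moleculeRef IRI text used to link the result to its molecule in
#'   RDF output.
#' @return a \code{DescriptorResult}.
#' @examples
#' descriptorValue(calcDescriptor(parseSmiles("C1CC1"), "ringCount"))
#' @export
calcDescriptor <- function(mol, id, params = list(),
                           moleculeRef = "http://example.com/mol1") {
  if (!exists(id, envir = descriptorRegistryEnv))
    stop("unknown descriptor id '", id, "'; registry holds: ",
         paste(sort(ls(descriptorRegistryEnv)), collapse = ", "))
  spec <- get(id, envir = descriptorRegistryEnv)
  unknown <- setdiff(names(params), names(spec$parameters))
  if (length(unknown))
    stop("unknown parameter(s) for ", id, ": ", paste(unknown, collapse = ", "))
  use <- spec$parameters
  use[names(params)] <- params
  value <- spec$fun(mol, use)
  new("DescriptorResult", moleculeRef = moleculeRef, id = id,
      dictionaryEntry = spec$dictionaryEntry, parameterValues = use,
      value = as.numeric(value),
      software = c(title = "chemrdf", version = chemrdfVersion()))
}

#' Serialize a DescriptorResult to RDF (BODO pattern)
#'
#' The result resource is linked to its dictionary entry with
#' \code{bodo:instanceOf}, to the molecule it describes, to one parameter
#' resource per declared parameter (name and value), and to a software
#' resource (title, version). The numeric value is written as an
#' \code{xsd:decimal} literal whose lexical form preserves the value
#' exactly.
#'
#' @param result a \code{DescriptorResult}.
#' @param base IRI under which the result/parameter/software resources are
#'   minted.
#' @return a \code{TripleStore}.
#' @export
resultToRDF <- function(result, base = "http://example.com/calc1") {
  base <- sub("/+$", "", base)
  res <- iri(base)
  s <- character(0); p <- character(0); o <- character(0)
  say <- function(su, pr, ob) {
    s[length(s) + 1L] <<- su; p[length(p) + 1L] <<- pr; o[length(o) + 1L] <<- ob
  }
  say(res, rdfTypeIRI(), bodoIRI("DescriptorValue"))
  say(res, bodoIRI("instanceOf"), iri(result@dictionaryEntry))
  say(res, bodoIRI("forMolecule"), iri(result@moleculeRef))
  say(res, bodoIRI("value"), decimalLiteral(result@value))
  pv <- result@parameterValues
  for (k in seq_along(pv)) {
    pIRI <- iri(paste0(base, "/parameter", k))
    say(res, bodoIRI("hasParameter"), pIRI)
    say(pIRI, rdfTypeIRI(), bodoIRI("Parameter"))
    say(pIRI, iri(paste0(RDFS_NS, "label")), literal(names(pv)[k]))
    v <- pv[[k]]
    say(pIRI, bodoIRI("parameterValue"),
        if (is.logical(v)) literal(tolower(as.character(v)))
        else literal(as.character(v)))
  }
  sw <- iri(paste0(base, "/software"))
  say(res, bodoIRI("executedBy"), sw)
  say(sw, rdfTypeIRI(), bodoIRI("Software"))
  say(sw, dcTitleIRI(), literal(result@software[["title"]]))
  say(sw, bodoIRI("version"), literal(result@software[["version"]]))
  tripleStore(s, p, o, prefixes = chemrdfPrefixes())
}

#' Read a DescriptorResult back from its RDF serialization
#'
#' @param store a \code{TripleStore} holding one BODO-pattern descriptor
#'   result graph.
#' @param resultIRI IRI text of the result resource; defaults to the single
#'   \code{bodo:DescriptorValue}-typed resource.
#' @return a \code{DescriptorResult}; the value and parameter map equal the
#'   serialized ones exactly.
#' @export
resultFromRDF <- function(store, resultIRI = NULL) {
  tr <- store@triples
  typed <- tr$subject[tr$predicate == rdfTypeIRI() &
                        tr$object == bodoIRI("DescriptorValue")]
  res <- if (is.null(resultIRI)) {
    if (length(typed) != 1L)
      stop("expected exactly one bodo:DescriptorValue resource, found ",
           length(typed))
    typed[1]
  } else iri(resultIRI)
  dict <- storeObjects(store, res, bodoIRI("instanceOf"))
  if (!length(dict)) stop("result has no bodo:instanceOf dictionary link")
  val <- storeObjects(store, res, bodoIRI("value"))
  if (!length(val)) stop("result has no bodo:value")
  params <- list()
  for (pIRI in storeObjects(store, res, bodoIRI("hasParameter"))) {
    nm <- literalValue(storeObjects(store, pIRI,
                                    iri(paste0(RDFS_NS, "label")))[1])
    raw <- literalValue(storeObjects(store, pIRI, bodoIRI("parameterValue"))[1])
    params[[nm]] <- if (raw %in% c("true", "false")) raw == "true"
                    else if (grepl("^-?[0-9.]+$", raw)) as.numeric(raw)
                    else raw
  }
  sw <- storeObjects(store, res, bodoIRI("executedBy"))
  title <- version <- NA_character_
  if (length(sw)) {
    tt <- storeObjects(store, sw[1], dcTitleIRI())
    vv <- storeObjects(store, sw[1], bodoIRI("version"))
    if (length(tt)) title <- literalValue(tt[1])
    if (length(vv)) version <- literalValue(vv[1])
  }
  molRef <- storeObjects(store, res, bodoIRI("forMolecule"))
  id <- sub(paste0("^", BODO_NS), "", iriValue(dict[1]))
  new("DescriptorResult",
      moleculeRef = if (length(molRef)) iriValue(molRef[1]) else NA_character_,
      id = id, dictionaryEntry = iriValue(dict[1]), parameterValues = params,
      value = as.numeric(literalValue(val[1])),
      software = c(title = title, version = version))
}

#' Descriptor matrix over a set of molecules
#'
#' @param mols list of \code{Molecule} objects.
#' @param ids character vector of registry descriptor ids.
#' @param params named list of per-descriptor parameter overrides.
#' @return list with \code{matrix} (n x p, NA where a calculation failed,
#'   with a warning naming the cell) and \code{metadata} (the registry rows
#'   for the requested ids).
#' @export
descriptorMatrix <- function(mols, ids, params = list()) {
  stopifnot(length(mols) >= 1L, length(ids) >= 1L)
  M <- matrix(NA_real_, nrow = length(mols), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    pj <- if (ids[j] %in% names(params)) params[[ids[j]]] else list()
    for (i in seq_along(mols)) {
      v <- tryCatch(descriptorValue(calcDescriptor(mols[[i]], ids[j], pj)),
                    error = function(e) {
                      warning("descriptor ", ids[j], " failed on molecule ",
                              i, ": ", conditionMessage(e), call. = FALSE)
                      NA_real_
                    })
      M[i, j] <- unname(v)
    }
    if (all(is.na(M[, j])))
      stop("descriptor '", ids[j], "' failed on every molecule")
  }
  meta <- descriptorRegistry()
  list(matrix = M, metadata = meta[match(ids, meta$id), , drop = FALSE])
}
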