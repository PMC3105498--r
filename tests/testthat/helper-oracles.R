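# Independent oracles and generators used across the suite. These stay
# deliberately naive (exhaustive enumeration, direct table scans) so they
# check the real implementations without sharing code paths with them.

# Brute-force SPARQL BGP oracle: try every assignment of store triples to
# the triple patterns and keep consistent variable bindings.
bruteForceBGP <- function(store, patterns) {
  tr <- triples(store)
  n <- nrow(tr)
  k <- length(patterns)
  vars <- unique(unlist(lapply(patterns, function(p)
    sub("^\\?", "", p[startsWith(p, "?")]))))
  rows <- list()
  idx <- rep(1L, k)
  repeat {
    binding <- list()
    ok <- TRUE
    for (j in seq_len(k)) {
      t <- tr[idx[j], ]
      slots <- c(t$subject, t$predicate, t$object)
      for (pos in 1:3) {
        pat <- patterns[[j]][pos]
        if (startsWith(pat, "?")) {
          v <- sub("^\\?", "", pat)
          if (is.null(binding[[v]])) binding[[v]] <- slots[pos]
          else if (binding[[v]] != slots[pos]) { ok <- FALSE; break }
        } else if (pat != slots[pos]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) rows[[length(rows) + 1L]] <- unlist(binding)[vars]
    # odometer over triple assignments
    j <- k
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= n) break
      idx[j] <- 1L
      j <- j - 1L
      if (j == 0L) break
    }
    if (j == 0L) break
  }
  if (!length(rows))
    return(data.frame(matrix(character(0), 0, length(vars),
                             dimnames = list(NULL, vars)),
                      stringsAsFactors = FALSE))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- vars
  unique(out)
}

sortedRows <- function(df) {
  if (!nrow(df)) return(character(0))
  unname(sort(apply(df[, sort(names(df)), drop = FALSE], 1, paste,
                    collapse = "\r")))
}

# random small RDF stores for round-trip / isomorphism properties
randomStore <- function(nTriples = NULL, nBlanks = 3L) {
  if (is.null(nTriples)) nTriples <- sample(1:25, 1L)
  iris <- iri(paste0("http://example.org/r", 1:8))
  preds <- iri(paste0("http://example.org/p", 1:5))
  blanks <- blankNode(paste0("n", seq_len(nBlanks)))
  randomLiteral <- function() {
    switch(sample(4, 1L),
           literal(paste(sample(letters, 5), collapse = "")),
           literal(sample(100L, 1L)),
           literal(round(runif(1) * 10, 3), datatype = paste0(
             "http://www.w3.org/2001/XMLSchema#", "decimal")),
           literal(paste(sample(letters, 3), collapse = ""), lang = "en"))
  }
  s <- p <- o <- character(nTriples)
  for (i in seq_len(nTriples)) {
    s[i] <- if (runif(1) < 0.25 && nBlanks) sample(blanks, 1L)
            else sample(iris, 1L)
    p[i] <- sample(preds, 1L)
    o[i] <- if (runif(1) < 0.2 && nBlanks) sample(blanks, 1L)
            else if (runif(1) < 0.5) sample(iris, 1L) else randomLiteral()
  }
  tripleStore(s, p, o,
              prefixes = c(ex = "http://example.org/",
                           xsd = "http://www.w3.org/2001/XMLSchema#"))
}

# consistently relabel the blank nodes of a store
relabelBlanks <- function(store, suffix = "renamed") {
  tr <- triples(store)
  bl <- unique(c(tr$subject[isTermBlank(tr$subject)],
                 tr$object[isTermBlank(tr$object)]))
  map <- setNames(blankNode(paste0(suffix, seq_along(bl))), bl)
  ms <- match(tr$subject, names(map)); mo <- match(tr$object, names(map))
  tr$subject <- ifelse(is.na(ms), tr$subject, map[ms])
  tr$object <- ifelse(is.na(mo), tr$object, map[mo])
  tripleStore(tr$subject, tr$predicate, tr$object,
              prefixes = storePrefixes(store))
}

# frozen external-toolkit oracle (RDKit values; '#' appears inside SMILES,
# so comment lines are stripped by hand)
readSmilesOracle <- function() {
  path <- testthat::test_path("fixtures", "smiles_oracle.tsv")
  lines <- readLines(path)
  read.delim(text = paste(lines[!startsWith(lines, "#")], collapse = "\n"),
             stringsAsFactors = FALSE)
}

randomMolecules <- function(n) lapply(randomSmiles(n), parseSmiles)

# permute the atom order of a molecule, remapping bonds accordingly
permuteAtoms <- function(mol, perm = sample(atomCount(mol))) {
  b <- bonds(mol)
  newIndex <- integer(atomCount(mol))
  newIndex[perm] <- seq_along(perm)  # old index -> new position
  b$atom1 <- newIndex[b$atom1]
  b$atom2 <- newIndex[b$atom2]
  molecule(atoms = atoms(mol)[perm, , drop = FALSE], bonds = b,
           name = moleculeName(mol))
}

# one shared synthetic ChEMBL store for the extraction/modeling tests
sharedChemblGen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateChemblStore(chemblSynthConfig(
        seed = 7L, nMolecules = 50L, activitiesPerTarget = 20L,
        nIonChannelTargets = 6L))
    cache
  }
})

fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "chemrdf")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", name)
  p
}
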