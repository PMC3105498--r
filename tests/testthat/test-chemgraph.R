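test_that("SMILES parsing handles bracket atoms, charges and hydrogens", {
  m <- parseSmiles("C[OH2+]")
  expect_equal(atomCount(m), 2L)
  expect_equal(bondCount(m), 1L)
  expect_equal(atoms(m)$charge, c(0L, 1L))
  expect_equal(atoms(m)$implicitH, c(3L, 2L))
  expect_equal(bonds(m)$order, "single")

  m1 <- parseSmiles("C")
  expect_equal(atomCount(m1), 1L)
  expect_equal(bondCount(m1), 0L)
  expect_equal(atoms(m1)$implicitH, 4L)

  benzene <- parseSmiles("c1ccccc1")
  expect_true(all(atoms(benzene)$aromatic))
  expect_equal(atoms(benzene)$implicitH, rep(1L, 6))
  expect_equal(bonds(benzene)$order, rep("aromatic", 6))
})

test_that("malformed SMILES raise structured errors naming the position", {
  expect_error(parseSmiles("CC(C"), "unbalanced parentheses")
  expect_error(parseSmiles("C1CC"), "unmatched ring closure")
  expect_error(parseSmiles("CXC"), "unknown element")
  expect_error(parseSmiles("C[Zn]C"), "unknown element")
  expect_error(parseSmiles("C=1CC#1"), "conflicting bond orders")
  expect_error(parseSmiles("C[C@H](N)O"), "unsupported bracket atom")
  err <- tryCatch(parseSmiles("CC)C"), error = function(e)
    conditionMessage(e))
  expect_match(err, "position 3")
})

test_that("atom/bond/formula/weight agree with the frozen toolkit oracle", {
  oracle <- readSmilesOracle()
  expect_equal(nrow(oracle), 200L)
  for (i in seq_len(nrow(oracle))) {
    m <- parseSmiles(oracle$smiles[i])
    expect_equal(atomCount(m), oracle$atoms[i], info = oracle$smiles[i])
    expect_equal(bondCount(m), oracle$bonds[i], info = oracle$smiles[i])
    expect_equal(molecularFormula(m), oracle$formula[i],
                 info = oracle$smiles[i])
    expect_lt(abs(molecularWeight(m) - oracle$molwt[i]), 0.02)
  }
})

test_that("implicit hydrogens complete the standard valence", {
  valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
               Cl = 1, Br = 1, I = 1)
  w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  set.seed(406)
  for (m in randomMolecules(60)) {
    a <- atoms(m); b <- bonds(m)
    used <- numeric(nrow(a))
    for (k in seq_len(nrow(b))) {
      used[b$atom1[k]] <- used[b$atom1[k]] + w[[b$order[k]]]
      used[b$atom2[k]] <- used[b$atom2[k]] + w[[b$order[k]]]
    }
    neutral <- a$charge == 0L
    expect_true(all(a$implicitH[neutral] ==
                      floor(valence[a$element[neutral]] - used[neutral])),
                info = m@smiles)
  }
})

test_that("molecule RDF carries one resource per atom and bond", {
  st <- moleculeToRDF(parseSmiles("C[OH2+]", name = "protonated methanol"))
  tr <- triples(st)
  typeP <- iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  expect_equal(sum(tr$predicate == typeP &
                     tr$object == iri("http://example.org/ontology/cdk#Atom")),
               2L)
  expect_equal(sum(tr$predicate == typeP &
                     tr$object == iri("http://example.org/ontology/cdk#Bond")),
               1L)
  # empty molecule: a molecule resource without atom links
  st0 <- moleculeToRDF(molecule())
  tr0 <- triples(st0)
  expect_equal(sum(tr0$predicate ==
                     iri("http://example.org/ontology/cdk#hasAtom")), 0L)
  expect_equal(sum(tr0$object ==
                     iri("http://example.org/ontology/cdk#Molecule")), 1L)
})

test_that("the CDK-model fixture reconstructs protonated methanol", {
  st <- readRDF(fixturePath("protonated_methanol.n3"))
  m <- moleculeFromRDF(st)
  expect_equal(molecularFormula(m), "CH5O")
  expect_equal(sum(atoms(m)$charge), 1L)
  expect_equal(atomCount(m), 2L)
  expect_equal(m@inchi, "InChI=1/CH4O/c1-2/h2H,1H3/p+1")
  expect_error(moleculeFromRDF(tripleStore()), "no cdk:Molecule")
})

test_that("molecule RDF round-trip preserves the graph exactly", {
  set.seed(407)
  mols <- randomMolecules(100)
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    m@name <- paste0("random molecule ", i)
    back <- moleculeFromRDF(moleculeToRDF(m))
    expect_true(sameStructure(m, back), info = m@smiles)
  }
})

test_that("InChI URIs follow the resolver convention and invert", {
  expect_equal(inchiToURI("InChI=1/CH4/h1H4"),
               "http://rdf.openmolecules.net/?InChI=1/CH4/h1H4")
  inchis <- c("InChI=1/CH4/h1H4", "InChI=1/C2H6O/c1-3-2/h1-2H3",
              "InChI=1/CH4O/c1-2/h2H,1H3/p+1")
  expect_equal(uriToInchi(inchiToURI(inchis)), inchis)
  expect_error(inchiToURI("CH4"), "InChI")
  expect_error(uriToInchi("http://other.example/?x=1"), "resolver URI")
  # configurable resolver base round-trips too
  alt <- inchiToURI("InChI=1/CH4/h1H4", base = "http://my.resolver/")
  expect_equal(uriToInchi(alt, base = "http://my.resolver/"),
               "InChI=1/CH4/h1H4")
})

test_that("formula and weight handle edge cases", {
  expect_equal(molecularFormula(parseSmiles("CO")), "CH4O")
  expect_equal(molecularFormula(molecule()), "")
  expect_equal(molecularWeight(molecule()), 0)
  expect_lt(abs(molecularWeight(parseSmiles("C")) - 16.04), 0.01)
  # Hill order without carbon: plain alphabetical
  expect_equal(molecularFormula(parseSmiles("O")), "H2O")
})

test_that("SD files re-read with an established toolkit", {
  skip_if_not_installed("ChemmineR")
  set.seed(408)
  mols <- randomMolecules(20)
  path <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(mols, path,
           properties = lapply(seq_along(mols), function(i)
             c(activity = i)))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  expect_equal(length(sdf), 20L)
  counts <- unname(vapply(ChemmineR::atomblock(sdf), nrow, integer(1)))
  expect_equal(counts, vapply(mols, atomCount, integer(1)))
})

test_that("SD counts line is bit-exact V2000 and limits enforced", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(list(parseSmiles("C[OH2+]", name = "protonated methanol")), path)
  lines <- readLines(path)
  expect_equal(lines[4], "  2  1  0  0  0  0  0  0  0  0999 V2000")
  expect_true(any(grepl("^M  CHG  1", lines)))
  # empty list gives an empty file
  writeSDF(list(), path)
  expect_equal(length(readLines(path)), 0L)
  big <- molecule(atoms = data.frame(element = rep("C", 1000L)))
  expect_error(writeSDF(list(big), path), "999")
})
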