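test_that("Turtle parsing captures asserted triples and prefixes", {
  st <- readRDF(fixturePath("methoxymethane.n3"))
  expect_equal(tripleCount(st), 7L)
  # the molecule resource is typed as a Molecule class
  tr <- triples(st)
  typeTriples <- tr[tr$predicate ==
                      iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"), ]
  expect_equal(typeTriples$object, iri("http://example.org/sdb#Molecule"))
  expect_true("sdb" %in% names(storePrefixes(st)))
  # and it links three external repositories through the resolver resource
  seeAlso <- tr[tr$predicate ==
                  iri("http://www.w3.org/2000/01/rdf-schema#seeAlso"), ]
  expect_equal(nrow(seeAlso), 3L)
})

test_that("empty and malformed documents behave as declared", {
  expect_equal(tripleCount(parseRDF("")), 0L)
  expect_equal(tripleCount(parseRDF("# only a comment")), 0L)
  err <- tryCatch(parseRDF("ex:a ex:b"), error = function(e)
    conditionMessage(e))
  expect_match(err, "line")
  expect_error(parseRDF("@prefix ex: <http://e.org/> .\nex:a ex:p (1 2) ."),
               "not supported")
})

test_that("serialize then parse is isomorphic for fixtures and random stores", {
  for (f in c("methoxymethane.n3", "protonated_methanol.n3",
              "tpsa_result.n3", "nmr_spectrum.n3")) {
    st <- readRDF(fixturePath(f))
    expect_true(isomorphic(st, parseRDF(serializeRDF(st))), info = f)
  }
  set.seed(401)
  for (i in 1:50) {
    st <- randomStore()
    expect_true(isomorphic(st, parseRDF(serializeRDF(st))),
                info = paste("random store", i))
  }
})

test_that("serializer output shape matches the store", {
  expect_equal(tripleCount(parseRDF(serializeRDF(tripleStore()))), 0L)
  st <- tripleStore(iri("http://e.org/s"), iri("http://e.org/p"),
                    literal("v"))
  txt <- serializeRDF(st)
  statements <- sum(grepl("\\.\\s*$",
                          grep("^@prefix", strsplit(txt, "\n")[[1]],
                               invert = TRUE, value = TRUE)))
  expect_equal(statements, 1L)
})

test_that("the DISTINCT-predicate query counts distinct predicates", {
  st <- tripleStore(iri(paste0("http://e.org/s", 1:3)),
                    iri(c("http://e.org/p", "http://e.org/p",
                          "http://e.org/q")),
                    literal(c("a", "b", "c")))
  res <- query(st, "SELECT DISTINCT ?predicate WHERE { [] ?predicate [] }")
  expect_equal(resultCount(res), 2L)
  expect_equal(resultCount(query(tripleStore(),
                                 "SELECT ?p WHERE { ?s ?p ?o }")), 0L)
})

test_that("BGP joins agree with exhaustive enumeration", {
  set.seed(402)
  pats <- list(
    list(c("?a", iri("http://example.org/p1"), "?b"),
         c("?b", iri("http://example.org/p2"), "?c")),
    list(c("?a", "?p", "?b"), c("?b", "?p", "?c")),
    list(c("?x", iri("http://example.org/p1"), "?y"),
         c("?x", iri("http://example.org/p2"), "?z")))
  for (rep in 1:6) {
    st <- randomStore(nTriples = 10L, nBlanks = 0L)
    for (patterns in pats) {
      sparqlPats <- vapply(patterns, function(p) paste(
        vapply(p, function(t) if (startsWith(t, "?")) t else t,
               character(1)), collapse = " "), character(1))
      vars <- unique(unlist(lapply(patterns, function(p)
        p[startsWith(p, "?")])))
      q <- paste0("SELECT DISTINCT ", paste(vars, collapse = " "),
                  " WHERE { ", paste(sparqlPats, collapse = " . "), " }")
      mine <- as.data.frame(resultBindings(query(st, q)))
      names(mine) <- sub("^\\?", "", vars)
      oracle <- bruteForceBGP(st, lapply(patterns, unlist))
      expect_setequal(sortedRows(unique(mine)), sortedRows(oracle))
    }
  }
})

test_that("query results do not depend on triple insertion order", {
  set.seed(403)
  st <- randomStore(nTriples = 15L, nBlanks = 0L)
  tr <- triples(st)
  perm <- sample(nrow(tr))
  st2 <- tripleStore(tr$subject[perm], tr$predicate[perm], tr$object[perm])
  q <- "SELECT ?s ?o WHERE { ?s <http://example.org/p1> ?o }"
  expect_setequal(sortedRows(resultBindings(query(st, q))),
                  sortedRows(resultBindings(query(st2, q))))
})

test_that("DISTINCT never increases the row count and LIMIT truncates", {
  set.seed(404)
  st <- randomStore(nTriples = 20L, nBlanks = 0L)
  qAll <- "SELECT ?p WHERE { ?s ?p ?o }"
  qDist <- "SELECT DISTINCT ?p WHERE { ?s ?p ?o }"
  expect_lte(resultCount(query(st, qDist)), resultCount(query(st, qAll)))
  expect_lte(resultCount(query(st, "SELECT ?p WHERE { ?s ?p ?o } LIMIT 3")),
             3L)
})

test_that("FILTER and OPTIONAL evaluate the supported subset", {
  doc <- '
  @prefix ex: <http://e.org/> .
  ex:a ex:v 3.5 ; ex:name "alpha" .
  ex:b ex:v 1.0 ; ex:name "beta" .
  ex:c ex:v 9.9 .
  '
  st <- parseRDF(doc)
  gt <- query(st, "PREFIX ex: <http://e.org/>
    SELECT ?s WHERE { ?s ex:v ?v FILTER (?v > 3) }")
  expect_equal(resultCount(gt), 2L)
  rx <- query(st, 'PREFIX ex: <http://e.org/>
    SELECT ?s WHERE { ?s ex:name ?n FILTER regex(?n, "^a") }')
  expect_equal(resultCount(rx), 1L)
  opt <- query(st, "PREFIX ex: <http://e.org/>
    SELECT ?s ?n WHERE { ?s ex:v ?v OPTIONAL { ?s ex:name ?n } }")
  df <- as.data.frame(opt)
  expect_equal(resultCount(opt), 3L)
  expect_equal(sum(is.na(df$n)), 1L)
})

test_that("unsupported SPARQL features fail loudly, never silently", {
  st <- tripleStore()
  expect_error(query(st, "SELECT * WHERE { ?s ?p ?o }"), "unsupported")
  expect_error(query(st, "SELECT ?s WHERE { ?s ?p ?o } ORDER BY ?s"),
               "unsupported")
  expect_error(query(st,
    "SELECT ?s WHERE { { ?s ?p ?o } UNION { ?o ?p ?s } }"), "unsupported")
  expect_error(selectVariables("ASK { ?s ?p ?o }"), "unsupported")
})

test_that("selectVariables returns the projection in order", {
  expect_equal(selectVariables("SELECT ?x WHERE { ?x ?p ?o }"), "x")
  qv <- selectVariables(qsarQueryText())
  expect_length(qv, 7L)
  expect_true(all(c("act", "smiles", "conf") %in% qv))
  pv <- selectVariables(pcmQueryText())
  expect_length(pv, 9L)
  expect_true(all(c("target", "seq") %in% pv))
})

test_that("isomorphism finds blank-node bijections and rejects mismatches", {
  set.seed(405)
  st <- randomStore(nTriples = 12L, nBlanks = 4L)
  expect_true(isomorphic(st, st))
  expect_true(isomorphic(st, relabelBlanks(st)))
  # change one literal
  tr <- triples(st)
  lit <- which(isTermLiteral(tr$object))[1]
  if (!is.na(lit)) {
    tr$object[lit] <- literal("changed-value-xyz")
    expect_false(isomorphic(st, tripleStore(tr$subject, tr$predicate,
                                            tr$object)))
  }
  # swapping blank roles must still be found by the exhaustive search
  doc1 <- "_:a <http://e.org/p> _:b . _:b <http://e.org/p> _:a ."
  doc2 <- "_:x <http://e.org/p> _:y . _:y <http://e.org/p> _:x ."
  expect_true(isomorphic(parseRDF(doc1), parseRDF(doc2)))
  doc3 <- "_:x <http://e.org/p> _:y . _:x <http://e.org/p> _:z ."
  expect_false(isomorphic(parseRDF(doc1), parseRDF(doc3)))
})

test_that("results export to CSV with empty cells for unbound variables", {
  st <- parseRDF('@prefix ex: <http://e.org/> . ex:a ex:v 1 .')
  res <- query(st, "PREFIX ex: <http://e.org/>
    SELECT ?s ?n WHERE { ?s ex:v ?v OPTIONAL { ?s ex:name ?n } }")
  path <- withr::local_tempfile(fileext = ".csv")
  writeResultCSV(res, path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(names(out), c("s", "n"))
  expect_equal(out$s, "http://e.org/a")
  expect_true(is.na(out$n) || out$n == "")
})
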