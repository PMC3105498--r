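Package: chemrdf
Title: RDF-Backed Cheminformatics and Molecular Chemometrics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bridges Resource Description Framework (RDF) representations of
    molecular knowledge with chemometric modelling. Provides an in-memory
    triple store with Turtle/Notation3 reading and writing and a SPARQL SELECT
    subset; a chemical-graph model with SMILES parsing, implicit-hydrogen
    bookkeeping, CDK-model RDF serialization, InChI-based identity URIs and
    MDL SD file export; molecular descriptors with full calculation provenance
    serialized after the Blue Obelisk Descriptor Ontology pattern; a seeded
    synthetic ChEMBL-like store with SPARQL extraction of QSAR and
    proteochemometric data sets; Bayesian weighted ridge regression of
    activity data by Gibbs sampling with cross-validated PRESS summaries;
    a proteochemometric pipeline (z-scale sequence encoding, PCA, ligand-
    protein cross-terms, NIPALS partial least squares with VIP ranking); and
    NMR spectral dereplication by chemical-shift peak matching over RDF
    spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Biostrings
Suggests: testthat (>= 3.0.0), withr, ChemmineR, mixOmics, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
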