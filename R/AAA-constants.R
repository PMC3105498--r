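# Namespace constants, defined first in collate order because the
# descriptor registry references them at load time.

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
DC_NS <- "http://purl.org/dc/elements/1.1/"

# Package-owned vocabularies. The class and property names mirror the
# published CDK-model / Blue Obelisk descriptor / ChEMBL-shaped / NMR
# descriptions, but the namespace IRIs are fixed by this package (the
# originals are not recoverable); see inst/extdata/vocabulary.ttl.
CDK_NS <- "http://example.org/ontology/cdk#"
BODO_NS <- "http://example.org/ontology/bodo#"
CHEMBL_NS <- "http://example.org/chembl#"
NMR_NS <- "http://example.org/nmr#"
SDB_NS <- "http://example.org/sdb#"
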