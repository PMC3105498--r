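# A 13C NMR spectrum with three peaks, tied to its molecule;
# shifts in ppm. Generated by chemrdf::spectrumToRDF().
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix dc: <http://purl.org/dc/elements/1.1/> .
@prefix cdk: <http://example.org/ontology/cdk#> .
@prefix bodo: <http://example.org/ontology/bodo#> .
@prefix chembl: <http://example.org/chembl#> .
@prefix nmr: <http://example.org/nmr#> .
@prefix sdb: <http://example.org/sdb#> .

<http://example.org/nmr/spectrum/s1> a nmr:Spectrum ;
    nmr:aboutMolecule <http://example.org/nmr/molecule/mol1> ;
    nmr:nucleus "13C" ;
    nmr:hasPeak <http://example.org/nmr/spectrum/s1/peak1> , <http://example.org/nmr/spectrum/s1/peak2> , <http://example.org/nmr/spectrum/s1/peak3> .

<http://example.org/nmr/spectrum/s1/peak1> a nmr:Peak ;
    nmr:shift "              23.5"^^xsd:decimal .

<http://example.org/nmr/spectrum/s1/peak2> a nmr:Peak ;
    nmr:shift "42.399999999999999"^^xsd:decimal .

<http://example.org/nmr/spectrum/s1/peak3> a nmr:Peak ;
    nmr:shift "211.90000000000001"^^xsd:decimal .

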