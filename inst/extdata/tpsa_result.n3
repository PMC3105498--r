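# Descriptor-provenance serialization (BODO pattern): a TPSA value
# linked to its dictionary entry, its checkAromaticity parameter
# (false: aromaticity was not re-detected) and the software that
# produced it. Generated by chemrdf::resultToRDF().
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

<http://example.com/calc1> a bodo:DescriptorValue ;
    bodo:instanceOf bodo:tpsa ;
    bodo:forMolecule <http://example.com/mol2> ;
    bodo:value "63.600000000000009"^^xsd:decimal ;
    bodo:hasParameter <http://example.com/calc1/parameter1> ;
    bodo:executedBy <http://example.com/calc1/software> .

<http://example.com/calc1/parameter1> a bodo:Parameter ;
    rdfs:label "checkAromaticity" ;
    bodo:parameterValue "false" .

<http://example.com/calc1/software> a bodo:Software ;
    dc:title "chemrdf" ;
    bodo:version "0.0.0" .

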