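# CDK-model serialization of protonated methanol: two atoms, one
# bond in one molecule, one atom positively charged, hydrogens
# implicit; identity link to the InChI resolver. Generated by
# chemrdf::moleculeToRDF() (reconstruction of the published example).
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

<http://example.com/mol1> a cdk:Molecule ;
    dc:title "protonated methanol" ;
    cdk:smiles "C[OH2+]" ;
    owl:sameAs <http://rdf.openmolecules.net/?InChI=1/CH4O/c1-2/h2H,1H3/p+1> ;
    cdk:hasAtom <http://example.com/mol1/atom1> , <http://example.com/mol1/atom2> ;
    cdk:hasBond <http://example.com/mol1/bond1> .

<http://example.com/mol1/atom1> a cdk:Atom ;
    cdk:symbol "C" ;
    cdk:index "1"^^xsd:integer ;
    cdk:implicitHydrogenCount "3"^^xsd:integer .

<http://example.com/mol1/atom2> a cdk:Atom ;
    cdk:symbol "O" ;
    cdk:index "2"^^xsd:integer ;
    cdk:implicitHydrogenCount "2"^^xsd:integer ;
    cdk:formalCharge "1"^^xsd:integer .

<http://example.com/mol1/bond1> a cdk:Bond ;
    cdk:bindsAtom <http://example.com/mol1/atom1> , <http://example.com/mol1/atom2> ;
    cdk:order "single" ;
    cdk:index "1"^^xsd:integer .

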