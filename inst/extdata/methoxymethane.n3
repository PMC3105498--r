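# Reconstruction of the small Notation3 network for methoxymethane: a
# molecule resource with a name and SMILES, an owl:sameAs identity link to
# the InChI resolver, and onward links to three external RDF repositories
# (NMRShiftDB, ChEBI, DBPedia) via that resolver resource. The dc:title
# "Methanol" next to the methoxymethane identity reproduces the original
# file verbatim; the discrepancy is documented, not resolved.
@prefix sdb: <http://example.org/sdb#> .
@prefix dc: <http://purl.org/dc/elements/1.1/> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

sdb:mol1 a sdb:Molecule ;
    dc:title "Methanol" ;
    sdb:smiles "CO" ;
    owl:sameAs <http://rdf.openmolecules.net/?InChI=1/C2H6O/c1-3-2/h1-2H3> .

<http://rdf.openmolecules.net/?InChI=1/C2H6O/c1-3-2/h1-2H3>
    rdfs:seeAlso <http://www.nmrshiftdb.org/molecule/234> ,
        <http://www.ebi.ac.uk/chebi/searchId.do?chebiId=CHEBI:28887> ,
        <http://dbpedia.org/resource/Dimethyl_ether> .
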