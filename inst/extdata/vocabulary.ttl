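# Vocabulary used by chemrdf RDF output. The class/property names mirror
# the published CDK-model and Blue Obelisk Descriptor Ontology
# descriptions; the namespace IRIs are fixed by this package (deliberate
# reconstructions -- the original documents printed no resolvable
# namespaces). This file doubles as the descriptor dictionary: one entry
# per registered descriptor algorithm.
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix cdk: <http://example.org/ontology/cdk#> .
@prefix bodo: <http://example.org/ontology/bodo#> .
@prefix chembl: <http://example.org/chembl#> .
@prefix nmr: <http://example.org/nmr#> .

# --- chemical graph (CDK data model) ---------------------------------------
cdk:Element a owl:Class .
cdk:AtomType a owl:Class ; rdfs:subClassOf cdk:Element .
cdk:Atom a owl:Class ; rdfs:subClassOf cdk:AtomType .
cdk:ElectronContainer a owl:Class .
cdk:Bond a owl:Class ; rdfs:subClassOf cdk:ElectronContainer .
cdk:AtomContainer a owl:Class .
cdk:Molecule a owl:Class ; rdfs:subClassOf cdk:AtomContainer .
cdk:hasAtom a rdf:Property ; rdfs:domain cdk:AtomContainer ; rdfs:range cdk:Atom .
cdk:hasBond a rdf:Property ; rdfs:domain cdk:AtomContainer ; rdfs:range cdk:Bond .
cdk:bindsAtom a rdf:Property ; rdfs:domain cdk:Bond ; rdfs:range cdk:Atom .
cdk:symbol a rdf:Property ; rdfs:domain cdk:Element .
cdk:order a rdf:Property ; rdfs:domain cdk:Bond .
cdk:index a rdf:Property .
cdk:formalCharge a rdf:Property ; rdfs:domain cdk:Atom .
cdk:implicitHydrogenCount a rdf:Property ; rdfs:domain cdk:Atom .
cdk:aromatic a rdf:Property .
cdk:smiles a rdf:Property ; rdfs:domain cdk:Molecule .

# --- descriptor provenance (BODO pattern) ----------------------------------
bodo:DescriptorValue a owl:Class .
bodo:Parameter a owl:Class .
bodo:Software a owl:Class .
bodo:instanceOf a rdf:Property .
bodo:forMolecule a rdf:Property .
bodo:hasParameter a rdf:Property .
bodo:parameterValue a rdf:Property .
bodo:value a rdf:Property .
bodo:executedBy a rdf:Property .
bodo:version a rdf:Property .

# --- descriptor dictionary --------------------------------------------------
bodo:heavyAtomCount a bodo:DescriptorAlgorithm ;
  rdfs:label "Heavy atom count" ;
  rdfs:comment "Number of non-hydrogen atoms in the chemical graph." .
bodo:bondCount a bodo:DescriptorAlgorithm ;
  rdfs:label "Bond count" ;
  rdfs:comment "Number of bonds between heavy atoms." .
bodo:ringCount a bodo:DescriptorAlgorithm ;
  rdfs:label "Ring count" ;
  rdfs:comment "Cyclomatic number: bonds - atoms + connected components." .
bodo:molecularWeight a bodo:DescriptorAlgorithm ;
  rdfs:label "Molecular weight" ;
  rdfs:comment "Sum of standard atomic weights, implicit hydrogens included." .
bodo:tpsa a bodo:DescriptorAlgorithm ;
  rdfs:label "Topological polar surface area" ;
  rdfs:comment "Sum of nitrogen/oxygen fragment surface contributions; the checkAromaticity parameter controls whether lowercase-SMILES aromaticity is revalidated against ring membership." .

# --- ChEMBL-shaped store ----------------------------------------------------
chembl:Target a owl:Class .
chembl:Assay a owl:Class .
chembl:Activity a owl:Class .
chembl:Molecule a owl:Class .
chembl:targetType a rdf:Property .
chembl:organism a rdf:Property .
chembl:classL1 a rdf:Property . chembl:classL2 a rdf:Property .
chembl:classL3 a rdf:Property . chembl:classL4 a rdf:Property .
chembl:classL5 a rdf:Property . chembl:classL6 a rdf:Property .
chembl:classL7 a rdf:Property .
chembl:sequence a rdf:Property .
chembl:hasConfidence a rdf:Property .
chembl:forTarget a rdf:Property .
chembl:onAssay a rdf:Property .
chembl:forMolecule a rdf:Property .
chembl:type a rdf:Property .
chembl:standardValue a rdf:Property .
chembl:standardUnit a rdf:Property .
chembl:pubmedId a rdf:Property .
chembl:smiles a rdf:Property .

# --- NMR spectra -------------------------------------------------------------
nmr:Spectrum a owl:Class .
nmr:Peak a owl:Class .
nmr:aboutMolecule a rdf:Property .
nmr:hasPeak a rdf:Property .
nmr:shift a rdf:Property ; rdfs:comment "Chemical shift in ppm." .
nmr:intensity a rdf:Property .
nmr:nucleus a rdf:Property .
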