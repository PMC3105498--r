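# Proteochemometric extraction query: nine properties per activity row --
# target and its type, PubMed id, classification levels 4-6, molecular
# SMILES (which identifies the molecule), activity value and the target's
# protein sequence. Only Ki and IC50 activities pass; the {L6} placeholder
# restricts the level-6 classification (e.g. to sodium channels) and is
# substituted by pcmQueryText().
PREFIX chembl: <http://example.org/chembl#>
SELECT ?target ?type ?pubmed ?l4 ?l5 ?l6 ?smiles ?val ?seq
WHERE {
  ?act a chembl:Activity ;
       chembl:type ?type ;
       chembl:onAssay ?ass ;
       chembl:forMolecule ?mol ;
       chembl:standardValue ?val ;
       chembl:pubmedId ?pubmed .
  ?ass chembl:forTarget ?target .
  ?target chembl:classL4 ?l4 ;
          chembl:classL5 ?l5 ;
          chembl:classL6 ?l6 ;
          chembl:sequence ?seq .
  ?mol chembl:smiles ?smiles .
  FILTER regex(?type, "^(Ki|IC50)$")
  FILTER regex(?l6, "{L6}")
}
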