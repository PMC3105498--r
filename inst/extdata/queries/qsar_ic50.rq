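# QSAR extraction query: activity, assay, molecule, SMILES, value, unit
# and assay confidence for a given target and activity type. The {TARGET}
# and {TYPE} placeholders are substituted by qsarQueryText().
PREFIX chembl: <http://example.org/chembl#>
SELECT ?act ?ass ?mol ?smiles ?val ?unit ?conf
WHERE {
  ?act a chembl:Activity ;
       chembl:type "{TYPE}" ;
       chembl:onAssay ?ass ;
       chembl:forMolecule ?mol ;
       chembl:standardValue ?val ;
       chembl:standardUnit ?unit .
  ?ass chembl:hasConfidence ?conf ;
       chembl:forTarget <http://example.org/chembl/target/{TARGET}> .
  ?mol chembl:smiles ?smiles .
}
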