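#!/usr/bin/env python
"""Regenerate tests/testthat/fixtures/smiles_oracle.tsv.

Reads one SMILES per line on stdin (produce them with
chemrdf::randomSmiles under seed 20260928, 200 unique structures) and
writes the RDKit reference values used as the frozen external-toolkit
oracle: heavy atom count, bond count, molecular formula, average
molecular weight and TPSA.

Usage:
  Rscript -e 'library(chemrdf); set.seed(20260928);
              writeLines(head(unique(randomSmiles(3000)), 200))' |
    python tools/make_smiles_fixtures.py > tests/testthat/fixtures/smiles_oracle.tsv
"""
import sys

from rdkit import Chem
from rdkit.Chem import Descriptors, rdMolDescriptors

print("# Frozen external-toolkit oracle: per-SMILES heavy atom count, bond")
print("# count, molecular formula, average molecular weight (Da) and TPSA")
print("# (A^2) computed once with RDKit on 200 structures from the package")
print("# SMILES generator (seed 20260928).")
print("smiles\tatoms\tbonds\tformula\tmolwt\ttpsa")
for smi in sys.stdin.read().split():
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        sys.stderr.write("skipping unparseable SMILES: %s\n" % smi)
        continue
    print("%s\t%d\t%d\t%s\t%.4f\t%.2f" % (
        smi, mol.GetNumAtoms(), mol.GetNumBonds(),
        rdMolDescriptors.CalcMolFormula(mol), Descriptors.MolWt(mol),
        Descriptors.TPSA(mol)))
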