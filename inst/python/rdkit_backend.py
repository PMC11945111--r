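"""Batch chemistry helper: RDKit operations over SMILES read from stdin.

Usage: python rdkit_backend.py <op>
  op = canon     -> canonical SMILES per line, "" if the line is not a valid
                    molecule under RDKit sanitization
       scaffold  -> canonical Bemis-Murcko scaffold SMILES per line ("" for
                    acyclic molecules, literal \t__INVALID__ marker column
                    for unparseable input)
       fp        -> space-separated 0-based on-bit indices of the Morgan
                    fingerprint (radius 2, 1024 bits); "__INVALID__" if the
                    molecule does not parse
       props     -> tab-separated QED, SAS, Crippen LogP; "__INVALID__" rows
                    for molecules that fail

One SMILES per input line; output lines align 1:1 with input lines.
"""

import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import AllChem, Crippen, QED
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

INVALID = "__INVALID__"


def parse(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def op_canon(smi):
    mol = parse(smi)
    return "" if mol is None else Chem.MolToSmiles(mol)


def op_scaffold(smi):
    mol = parse(smi)
    if mol is None:
        return INVALID
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf is None or scaf.GetNumAtoms() == 0:
        return ""
    return Chem.MolToSmiles(scaf)


def op_fp(smi):
    mol = parse(smi)
    if mol is None:
        return INVALID
    fp = AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=1024)
    return " ".join(str(b) for b in fp.GetOnBits())


def op_props(smi):
    mol = parse(smi)
    if mol is None:
        return INVALID
    return "%.10g\t%.10g\t%.10g" % (
        QED.qed(mol),
        sascorer.calculateScore(mol),
        Crippen.MolLogP(mol),
    )


OPS = {"canon": op_canon, "scaffold": op_scaffold, "fp": op_fp, "props": op_props}


def main():
    if len(sys.argv) != 2 or sys.argv[1] not in OPS:
        sys.stderr.write("usage: rdkit_backend.py {canon|scaffold|fp|props}\n")
        return 2
    fn = OPS[sys.argv[1]]
    out = []
    for line in sys.stdin:
        out.append(fn(line.strip()))
    sys.stdout.write("\n".join(out) + ("\n" if out else ""))
    return 0


if __name__ == "__main__":
    sys.exit(main())
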