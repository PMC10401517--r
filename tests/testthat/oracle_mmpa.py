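#!/usr/bin/env python
"""Test-only oracle: reference matched-pair fragmentation via RDKit's rdMMPA.

Reads {"records": [{"id","smiles"},...], "max_cuts": k,
       "mine": [{"id","constant","variable","n_cuts"}, ...]}
and writes, per molecule, two label-normalized fragmentation sets:

  reference: enumerated independently by rdkit.Chem.rdMMPA.FragmentMol
             (an implementation of the Hussain-Rea scheme the mmpdb
             platform builds on)
  mine:      the package's fragmentations, re-canonicalized the same way

Label normalization (attachment maps stripped, fragments re-canonicalized,
multi-fragment constants in RDKit fragment order) is shared; the enumeration
under test is not: the package's fragmenter never calls rdMMPA.
Hydrogen-substitution records are excluded here (rdMMPA does not emit them);
they are checked by hand-derived cases instead.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMMPA

RDLogger.DisableLog("rdApp.*")


def normalize(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparseable fragment: %r" % smiles)
    for atom in mol.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetAtomMapNum(0)
            atom.SetIsotope(0)
    return Chem.MolToSmiles(mol)


def n_dummies(smiles):
    mol = Chem.MolFromSmiles(smiles)
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() == 0)


def reference_set(smiles, max_cuts):
    mol = Chem.MolFromSmiles(smiles)
    Chem.RemoveStereochemistry(mol)
    out = set()
    for core, chains in rdMMPA.FragmentMol(mol, maxCuts=max_cuts,
                                           resultsAsMols=False):
        if core == "":
            a, b = chains.split(".")
            out.add((normalize(b), normalize(a), 1))
            out.add((normalize(a), normalize(b), 1))
        else:
            out.add((normalize(chains), normalize(core), n_dummies(core)))
    return out


def main(argv):
    req = json.load(open(argv[1]))
    max_cuts = int(req.get("max_cuts", 3))
    mine = {}
    for f in req.get("mine", []):
        if f["variable"].startswith("[H]"):
            continue
        mine.setdefault(f["id"], set()).add(
            (normalize(f["constant"]), normalize(f["variable"]),
             int(f["n_cuts"])))
    out = []
    for rec in req["records"]:
        ref = reference_set(rec["smiles"], max_cuts)
        own = mine.get(rec["id"], set())
        fmt = lambda s: sorted("%s>>%s|%d" % t for t in s)
        out.append({"id": rec["id"],
                    "reference": fmt(ref),
                    "mine": fmt(own),
                    "match": sorted(ref) == sorted(own),
                    "missing_from_mine": fmt(ref - own),
                    "extra_in_mine": fmt(own - ref)})
    json.dump({"ok": True, "result": out}, open(argv[2], "w"))
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
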