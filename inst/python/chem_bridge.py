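#!/usr/bin/env python
"""RDKit bridge for the sascliffs R package.

Called as:  python chem_bridge.py <op> <request.json> <response.json>

Every op reads a JSON request and writes {"ok": true, "result": ...} or
{"ok": false, "error": "..."}. The R side does all analysis; this script only
provides molecular primitives: standardization, fingerprints, scaffold /
R-group description, and matched-molecular-pair fragment enumeration.

All structure keys produced here are RDKit canonical SMILES with
stereochemistry stripped (the workflow is deliberately stereo-insensitive).
"""

import itertools
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

# Counter-ions and solvents treated as salt components: stripped when at least
# one other fragment remains. Deliberately inorganic-only (plus water/ammonia):
# organic acids/bases such as acetate are kept as the parent structure.
SALT_SMILES = [
    "[Na+]", "[K+]", "[Li+]", "[Cs+]", "[NH4+]",
    "[Ca+2]", "[Mg+2]", "[Zn+2]", "[Ba+2]", "[Sr+2]", "[Fe+2]", "[Fe+3]",
    "[Al+3]", "[Ag+]", "[Cu+2]", "[Mn+2]", "[Ni+2]",
    "[Cl-]", "[Br-]", "[I-]", "[F-]", "Cl", "Br", "I", "F",
    "[OH-]", "O", "N",
    "[O-][N+](=O)[O-]", "O[N+](=O)[O-]",
    "[O-]S(=O)(=O)[O-]", "OS(=O)(=O)O", "OS(=O)(=O)[O-]",
    "[O-]P(=O)([O-])[O-]", "OP(=O)(O)O",
    "[O-]C(=O)[O-]", "OC(=O)O", "OC(=O)[O-]",
    "[O-][Cl+3]([O-])([O-])[O-]",
]
_SALT_SET = None


def salt_set():
    global _SALT_SET
    if _SALT_SET is None:
        _SALT_SET = set()
        for s in SALT_SMILES:
            m = Chem.MolFromSmiles(s)
            if m is not None:
                _SALT_SET.add(Chem.MolToSmiles(m))
    return _SALT_SET


def strip_stereo_smiles(mol):
    m = Chem.Mol(mol)
    Chem.RemoveStereochemistry(m)
    return Chem.MolToSmiles(m)


def n_heavy(mol):
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1)


# ---------------------------------------------------------------- standardize

def op_standardize(req):
    uncharger = rdMolStandardize.Uncharger()
    out = []
    for rec in req["records"]:
        smi = rec.get("smiles") or ""
        row = {"id": rec.get("id")}
        mol = Chem.MolFromSmiles(smi) if smi.strip() else None
        if mol is None:
            row["status"] = "invalid"
            out.append(row)
            continue
        frag_smis = [Chem.MolToSmiles(f)
                     for f in Chem.GetMolFrags(mol, asMols=True)]
        keep = sorted(set(frag_smis) - salt_set())
        if len(keep) == 0:
            row["status"] = "invalid"      # nothing but salt components
        elif len(keep) > 1:
            row["status"] = "mixture"
        else:
            m = Chem.MolFromSmiles(keep[0])
            m = uncharger.uncharge(m)
            if m is None or n_heavy(m) == 0:
                row["status"] = "invalid"
            else:
                row["status"] = "ok"
                row["canonical_smiles"] = strip_stereo_smiles(m)
                row["smiles_stereo"] = Chem.MolToSmiles(m)
                row["heavy_atoms"] = n_heavy(m)
                row["n_rings"] = m.GetRingInfo().NumRings()
        out.append(row)
    return out


# ---------------------------------------------------------------- fingerprint

def op_fingerprint(req):
    n_bits = int(req.get("n_bits", 2048))
    gen = AllChem.GetMorganGenerator(radius=2, fpSize=n_bits)
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append(None)
            continue
        bv = gen.GetFingerprint(mol)
        out.append([int(b) for b in bv.GetOnBits()])
    return {"n_bits": n_bits, "bits": out}


# ------------------------------------------------------------------- describe

def scaffold_atom_set(mol, scaffold):
    """Atom indices of mol belonging to its Bemis-Murcko scaffold."""
    match = mol.GetSubstructMatch(scaffold)
    if match:
        return set(match)
    # fallback: iteratively prune terminal atoms not in rings and not
    # multiply-bonded to a kept atom (matches the Murcko definition)
    keep = set(range(mol.GetNumAtoms()))
    changed = True
    while changed:
        changed = False
        for idx in list(keep):
            atom = mol.GetAtomWithIdx(idx)
            if atom.IsInRing():
                continue
            nbrs = [n.GetIdx() for n in atom.GetNeighbors()
                    if n.GetIdx() in keep]
            if len(nbrs) <= 1:
                bond_ok = True
                if nbrs:
                    b = mol.GetBondBetweenAtoms(idx, nbrs[0])
                    if b.GetBondType() != Chem.BondType.SINGLE:
                        bond_ok = False
                if bond_ok:
                    keep.discard(idx)
                    changed = True
    return keep


def genericize_smiles(mol):
    """Cyclic skeleton: every non-dummy atom -> carbon, every bond -> single."""
    rw = Chem.RWMol(mol)
    for atom in rw.GetAtoms():
        if atom.GetAtomicNum() != 0:
            atom.SetAtomicNum(6)
        atom.SetFormalCharge(0)
        atom.SetIsAromatic(False)
        atom.SetNumExplicitHs(0)
        atom.SetNoImplicit(False)
    for bond in rw.GetBonds():
        bond.SetBondType(Chem.BondType.SINGLE)
        bond.SetIsAromatic(False)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception:
        # hypervalent after genericization (e.g. ring sulfone): serialize
        # without implicit-H bookkeeping; still a deterministic topology key
        for atom in m.GetAtoms():
            atom.SetNoImplicit(True)
        m.UpdatePropertyCache(strict=False)
        Chem.GetSymmSSSR(m)
    return Chem.MolToSmiles(m)


def build_decorated_scaffold(mol, scaf_atoms, attachments, labels=None):
    """Scaffold subgraph with one dummy atom per attachment point.

    labels, if given, are isotope numbers carried by the dummies (used to
    encode which R-group sits at which site)."""
    rw = Chem.RWMol(mol)
    for k, (s, a, btype) in enumerate(attachments):
        d = rw.AddAtom(Chem.Atom(0))
        if labels is not None:
            rw.GetAtomWithIdx(d).SetIsotope(labels[k])
        rw.AddBond(s, d, btype)
    drop = [i for i in range(mol.GetNumAtoms()) if i not in scaf_atoms]
    for i in sorted(drop, reverse=True):
        rw.RemoveAtom(i)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception:
        m.UpdatePropertyCache(strict=False)
        Chem.GetSymmSSSR(m)
    return m


def rgroup_smiles(mol, comp, s):
    """Canonical SMILES of one R-group: component atoms plus the scaffold
    attachment atom replaced by a dummy."""
    rw = Chem.RWMol(mol)
    atom = rw.GetAtomWithIdx(s)
    atom.SetAtomicNum(0)
    atom.SetFormalCharge(0)
    atom.SetIsAromatic(False)
    atom.SetNumExplicitHs(0)
    atom.SetNoImplicit(True)
    keep = set(comp) | {s}
    drop = [i for i in range(mol.GetNumAtoms()) if i not in keep]
    for i in sorted(drop, reverse=True):
        rw.RemoveAtom(i)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception:
        m.UpdatePropertyCache(strict=False)
        Chem.GetSymmSSSR(m)
    return Chem.MolToSmiles(m)


def op_describe(req):
    out = []
    for rec in req["records"]:
        row = {"id": rec.get("id")}
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            row["status"] = "invalid"
            out.append(row)
            continue
        Chem.RemoveStereochemistry(mol)
        scaffold = MurckoScaffold.GetScaffoldForMol(mol)
        if scaffold is None or scaffold.GetNumAtoms() == 0:
            row["status"] = "acyclic"
            out.append(row)
            continue
        scaf_atoms = scaffold_atom_set(mol, scaffold)
        # attachment bonds: scaffold atom -- side-chain atom
        attachments = []
        for b in mol.GetBonds():
            i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
            if (i in scaf_atoms) != (j in scaf_atoms):
                s, a = (i, j) if i in scaf_atoms else (j, i)
                attachments.append((s, a, b.GetBondType()))
        # side-chain connected components (acyclic by construction)
        side = [i for i in range(mol.GetNumAtoms()) if i not in scaf_atoms]
        comp_of = {}
        for start in side:
            if start in comp_of:
                continue
            stack, comp = [start], []
            comp_of[start] = comp
            while stack:
                x = stack.pop()
                comp.append(x)
                for nb in mol.GetAtomWithIdx(x).GetNeighbors():
                    k = nb.GetIdx()
                    if k not in scaf_atoms and k not in comp_of:
                        comp_of[k] = comp
                        stack.append(k)
        rgroups = [rgroup_smiles(mol, comp_of[a], s)
                   for (s, a, _) in attachments]
        distinct = sorted(set(rgroups))
        labels = [distinct.index(r) + 1 for r in rgroups]
        plain = build_decorated_scaffold(mol, scaf_atoms, attachments)
        lab = build_decorated_scaffold(mol, scaf_atoms, attachments, labels)
        row.update({
            "status": "ok",
            "scaffold": Chem.MolToSmiles(scaffold),
            "skeleton": genericize_smiles(scaffold),
            "rgroups": sorted(rgroups),
            "scaffold_sig": Chem.MolToSmiles(lab),
            "skeleton_sig": genericize_smiles(lab),
            "n_attachments": len(attachments),
        })
        out.append(row)
    return out


# ------------------------------------------------------------------- fragment

CUT_SMARTS = Chem.MolFromSmarts("[#6+0;!$(*=,#[!#6])]!@!=!#[*]")
H_ANCHOR_SMARTS = Chem.MolFromSmarts("[#6+0;!$(*=,#[!#6])]")


def cuttable_bonds(mol):
    bonds = set()
    for i, j in mol.GetSubstructMatches(CUT_SMARTS):
        b = mol.GetBondBetweenAtoms(i, j)
        if b.GetEndAtom().GetAtomicNum() > 1 and \
           b.GetBeginAtom().GetAtomicNum() > 1:
            bonds.add(b.GetIdx())
    return sorted(bonds)


def components_after_cut(mol, cut):
    """Connected components of the atom graph with the cut bonds removed."""
    n = mol.GetNumAtoms()
    parent = list(range(n))

    def find(x):
        while parent[x] != x:
            parent[x] = parent[parent[x]]
            x = parent[x]
        return x

    cut = set(cut)
    for b in mol.GetBonds():
        if b.GetIdx() in cut:
            continue
        ri, rj = find(b.GetBeginAtomIdx()), find(b.GetEndAtomIdx())
        if ri != rj:
            parent[ri] = rj
    comp = {}
    for i in range(n):
        comp.setdefault(find(i), []).append(i)
    return list(comp.values())


def relabel_smiles(frag_mol, perm):
    m = Chem.Mol(frag_mol)
    for atom in m.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetAtomMapNum(perm[atom.GetIsotope()])
            atom.SetIsotope(0)
    return Chem.MolToSmiles(m)


def canonical_fragmentation(var_mol, const_mols, k):
    """Choose the attachment-label permutation that minimizes the constant
    part's canonical SMILES (ties: the variable part's), so that identical
    constants always carry identical labels."""
    best = None
    for perm_tuple in itertools.permutations(range(1, k + 1)):
        perm = {i + 1: perm_tuple[i] for i in range(k)}
        const = ".".join(sorted(relabel_smiles(m, perm) for m in const_mols))
        var = relabel_smiles(var_mol, perm)
        key = (const, var)
        if best is None or key < best:
            best = key
    return best


def fragment_one(mol, max_cuts, with_h):
    results = {}
    bonds = cuttable_bonds(mol)
    heavy_parent = n_heavy(mol)
    for k in range(1, max_cuts + 1):
        for cut in itertools.combinations(bonds, k):
            comps = components_after_cut(mol, cut)
            if len(comps) != k + 1:
                continue   # a cut bond was inside a cycle of chosen bonds
            # count cut bonds touching each component
            touch = []
            bond_atoms = [(mol.GetBondWithIdx(b).GetBeginAtomIdx(),
                           mol.GetBondWithIdx(b).GetEndAtomIdx())
                          for b in cut]
            for comp in comps:
                cs = set(comp)
                touch.append(sum((i in cs) or (j in cs)
                                 for (i, j) in bond_atoms))
            if k >= 2:
                # valid only when a single (variable) fragment carries all cuts
                if touch.count(k) != 1 or touch.count(1) != k:
                    continue
            frag = Chem.FragmentOnBonds(
                mol, list(cut), addDummies=True,
                dummyLabels=[(c + 1, c + 1) for c in range(k)])
            try:
                frag_mols = Chem.GetMolFrags(frag, asMols=True,
                                             sanitizeFrags=True)
            except Exception:
                continue
            n_dummies = [sum(1 for a in fm.GetAtoms()
                             if a.GetAtomicNum() == 0) for fm in frag_mols]
            if k == 1:
                orientations = [(0, 1), (1, 0)]
            else:
                vi = n_dummies.index(k)
                orientations = [(vi, None)]
            for ori in orientations:
                if k == 1:
                    vi, ci = ori
                    var_mol = frag_mols[vi]
                    const_mols = [frag_mols[ci]]
                else:
                    vi = ori[0]
                    var_mol = frag_mols[vi]
                    const_mols = [fm for t, fm in enumerate(frag_mols)
                                  if t != vi]
                const, var = canonical_fragmentation(var_mol, const_mols, k)
                vh = n_heavy(var_mol)
                results[(const, var)] = {
                    "constant": const, "variable": var, "n_cuts": k,
                    "constant_heavy": heavy_parent - vh, "variable_heavy": vh,
                }
    if with_h:
        # hydrogen substitution: one single-cut fragmentation per H on an
        # eligible anchor atom; variable part is a labelled hydrogen
        anchors = {i for (i,) in mol.GetSubstructMatches(H_ANCHOR_SMARTS)}
        for i in sorted(anchors):
            if mol.GetAtomWithIdx(i).GetTotalNumHs() < 1:
                continue
            rw = Chem.RWMol(mol)
            d = rw.AddAtom(Chem.Atom(0))
            rw.GetAtomWithIdx(d).SetAtomMapNum(1)
            rw.AddBond(i, d, Chem.BondType.SINGLE)
            m = rw.GetMol()
            try:
                Chem.SanitizeMol(m)
            except Exception:
                continue
            const = Chem.MolToSmiles(m)
            results[(const, "[H][*:1]")] = {
                "constant": const, "variable": "[H][*:1]", "n_cuts": 1,
                "constant_heavy": heavy_parent, "variable_heavy": 0,
            }
    return list(results.values())


def op_fragment(req):
    max_cuts = int(req.get("max_cuts", 3))
    with_h = bool(req.get("hydrogen", True))
    out = []
    for rec in req["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            out.append({"id": rec.get("id"), "status": "invalid",
                        "fragmentations": []})
            continue
        Chem.RemoveStereochemistry(mol)
        out.append({"id": rec.get("id"), "status": "ok",
                    "fragmentations": fragment_one(mol, max_cuts, with_h)})
    return out


OPS = {
    "standardize": op_standardize,
    "fingerprint": op_fingerprint,
    "describe": op_describe,
    "fragment": op_fragment,
}


def main(argv):
    if len(argv) != 4 or argv[1] not in OPS:
        sys.stderr.write("usage: chem_bridge.py {%s} in.json out.json\n"
                         % "|".join(OPS))
        return 2
    with open(argv[2]) as fh:
        req = json.load(fh)
    try:
        result = {"ok": True, "result": OPS[argv[1]](req)}
    except Exception as exc:    # surfaced as an R condition by the caller
        result = {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}
    with open(argv[3], "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
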