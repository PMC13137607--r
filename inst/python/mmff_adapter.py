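"""MMFF94 typing adapter.

Reads a JSON request on stdin, writes a JSON response on stdout. The R
package uses this script for everything that requires the RDKit toolkit:

  * embed            -- SMILES -> 3D mol blocks (ETKDG, explicit H, seeded)
  * parameterize     -- mol block -> full MMFF94 parameter tables (bond,
                        angle, stretch-bend, out-of-plane, torsion, vdW,
                        partial charges) plus the nonbonded pair topology,
                        serialized as a neutral table set. The energy and
                        gradient kernels that consume these tables live in R.
  * reference_energy -- RDKit's own MMFF94 single-point energy (used as an
                        independent cross-check of the R kernels)
  * reference_minimize -- RDKit's MMFF94 minimizer (cross-check oracle)
  * pdb_gasteiger    -- fallback partial charges for pockets without a
                        charge sidecar
  * convert          -- any RDKit-readable mol block (e.g. V3000) -> V2000

All atom indices in the response are 1-based for direct use in R.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def _mol_from_block(block, sanitize=True):
    return Chem.MolFromMolBlock(block, sanitize=sanitize, removeHs=False)


def parameterize_one(block):
    mol = _mol_from_block(block)
    if mol is None:
        return {"error": "mol block failed to parse or sanitize", "atom": -1}
    if mol.GetNumConformers() == 0:
        return {"error": "no conformer present", "atom": -1}
    if AllChem.MMFFHasAllMoleculeParams(mol) is False:
        # locate the first untypable atom for diagnostics
        bad = -1
        try:
            AllChem.MMFFGetMoleculeProperties(mol)
        except Exception:
            pass
        for atom in mol.GetAtoms():
            if atom.GetAtomicNum() not in (
                1, 3, 5, 6, 7, 8, 9, 11, 12, 14, 15, 16, 17, 19, 20,
                26, 29, 30, 35, 53,
            ):
                bad = atom.GetIdx() + 1
                break
        return {"error": "MMFF94 atom typing failed", "atom": bad}
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        return {"error": "MMFF94 atom typing failed", "atom": -1}

    n = mol.GetNumAtoms()
    conf = mol.GetConformer()
    coords = [list(conf.GetAtomPosition(i)) for i in range(n)]
    elements = [a.GetSymbol() for a in mol.GetAtoms()]
    types = [props.GetMMFFAtomType(i) for i in range(n)]
    charges = [props.GetMMFFPartialCharge(i) for i in range(n)]
    formal = [a.GetFormalCharge() for a in mol.GetAtoms()]

    bonds = []
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        p = props.GetMMFFBondStretchParams(mol, i, j)
        if p is None:
            continue
        bonds.append([i + 1, j + 1, p[1], p[2]])

    nbrs = [sorted(a.GetIdx() for a in atom.GetNeighbors())
            for atom in mol.GetAtoms()]

    angles = []
    sbs = []
    bond_r0 = {}
    for i1, j1, kb, r0 in bonds:
        bond_r0[(i1 - 1, j1 - 1)] = r0
        bond_r0[(j1 - 1, i1 - 1)] = r0
    for j in range(n):
        ns = nbrs[j]
        for a in range(len(ns)):
            for b in range(a + 1, len(ns)):
                i, k = ns[a], ns[b]
                p = props.GetMMFFAngleBendParams(mol, i, j, k)
                if p is None:
                    continue
                theta0 = p[2]
                linear = 1 if abs(theta0 - 180.0) < 1e-9 else 0
                angles.append([i + 1, j + 1, k + 1, p[1], theta0, linear])
                sp = props.GetMMFFStretchBendParams(mol, i, j, k)
                if sp is not None and (i, j) in bond_r0 and (k, j) in bond_r0:
                    sbs.append([i + 1, j + 1, k + 1, sp[1], sp[2],
                                bond_r0[(i, j)], bond_r0[(k, j)], theta0])

    oops = []
    for j in range(n):
        ns = nbrs[j]
        if len(ns) != 3:
            continue
        a, b, c = ns
        for (i, k, l) in ((a, b, c), (a, c, b), (b, c, a)):
            p = props.GetMMFFOopBendParams(mol, i, j, k, l)
            if p is None:
                continue
            oops.append([i + 1, j + 1, k + 1, l + 1, p])

    torsions = []
    for bond in mol.GetBonds():
        j, k = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        for i in nbrs[j]:
            if i == k:
                continue
            for l in nbrs[k]:
                if l == j or l == i:
                    continue
                p = props.GetMMFFTorsionParams(mol, i, j, k, l)
                if p is None:
                    continue
                torsions.append([i + 1, j + 1, k + 1, l + 1,
                                 p[1], p[2], p[3]])

    dmat = Chem.GetDistanceMatrix(mol)
    vdw_pairs = []
    elec_pairs = []
    excl12 = []
    excl13 = []
    for i in range(n):
        for j in range(i + 1, n):
            d = dmat[i][j]
            if d == 1:
                excl12.append([i + 1, j + 1])
            elif d == 2:
                excl13.append([i + 1, j + 1])
            else:
                p = props.GetMMFFVdWParams(i, j)
                vdw_pairs.append([i + 1, j + 1, p[2], p[3]])
                scale = 0.75 if d == 3 else 1.0
                elec_pairs.append([i + 1, j + 1, scale])

    vdw_self = []
    for i in range(n):
        p = props.GetMMFFVdWParams(i, i)
        vdw_self.append([p[2], p[3]])

    return {
        "natoms": n,
        "elements": elements,
        "coords": coords,
        "atom_types": types,
        "charges": charges,
        "formal_charges": formal,
        "bonds": bonds,
        "angles": angles,
        "stretch_bends": sbs,
        "oops": oops,
        "torsions": torsions,
        "vdw_pairs": vdw_pairs,
        "elec_pairs": elec_pairs,
        "vdw_self": vdw_self,
        "excluded_12": excl12,
        "excluded_13": excl13,
    }


def reference_energy_one(block, coords=None, terms=False):
    mol = _mol_from_block(block)
    if mol is None:
        return {"error": "parse failure"}
    if coords is not None:
        conf = mol.GetConformer()
        for i, xyz in enumerate(coords):
            conf.SetAtomPosition(i, xyz)
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        return {"error": "typing failure"}
    ff = AllChem.MMFFGetMoleculeForceField(mol, props)
    out = {"energy": ff.CalcEnergy()}
    if terms:
        flags = ["Bond", "Angle", "StretchBend", "Oop", "Torsion", "VdW",
                 "Ele"]
        breakdown = {}
        for keep in flags:
            p2 = AllChem.MMFFGetMoleculeProperties(mol)
            for f in flags:
                getattr(p2, "SetMMFF" + ("EleTerm" if f == "Ele"
                                         else f + "Term"))(f == keep)
            ff2 = AllChem.MMFFGetMoleculeForceField(mol, p2)
            breakdown[keep] = ff2.CalcEnergy()
        out["terms"] = breakdown
    return out


def reference_minimize_one(block, max_its=2000):
    mol = _mol_from_block(block)
    if mol is None:
        return {"error": "parse failure"}
    props = AllChem.MMFFGetMoleculeProperties(mol)
    ff = AllChem.MMFFGetMoleculeForceField(mol, props)
    converged = ff.Minimize(maxIts=max_its, energyTol=1e-8, forceTol=1e-6)
    conf = mol.GetConformer()
    return {
        "energy": ff.CalcEnergy(),
        "converged": int(converged == 0),
        "molblock": Chem.MolToMolBlock(mol, kekulize=True),
        # mol blocks truncate to 1e-4 A; keep full precision for gradients
        "coords": [list(conf.GetAtomPosition(i))
                   for i in range(mol.GetNumAtoms())],
    }


def handle(req):
    mode = req["mode"]
    if mode == "embed":
        seed = int(req.get("seed", 0))
        out = []
        for idx, smi in enumerate(req["smiles"]):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append(None)
                continue
            mol = Chem.AddHs(mol)
            ps = AllChem.ETKDGv3()
            ps.randomSeed = (seed + 7919 * idx) % (2 ** 31 - 1)
            if AllChem.EmbedMolecule(mol, ps) != 0:
                out.append(None)
                continue
            out.append(Chem.MolToMolBlock(mol, kekulize=True))
        return {"molblocks": out}
    if mode == "parameterize":
        return {"params": [parameterize_one(b) for b in req["molblocks"]]}
    if mode == "reference_energy":
        coords = req.get("coords")
        res = []
        for i, b in enumerate(req["molblocks"]):
            c = coords[i] if coords is not None else None
            res.append(reference_energy_one(b, c, req.get("terms", False)))
        return {"results": res}
    if mode == "reference_minimize":
        its = int(req.get("max_its", 2000))
        return {"results": [reference_minimize_one(b, its)
                            for b in req["molblocks"]]}
    if mode == "pdb_gasteiger":
        mol = Chem.MolFromPDBBlock(req["pdb"], sanitize=False, removeHs=False)
        if mol is None:
            return {"charges": None}
        try:
            Chem.SanitizeMol(
                mol, Chem.SanitizeFlags.SANITIZE_ALL
                ^ Chem.SanitizeFlags.SANITIZE_KEKULIZE)
            AllChem.ComputeGasteigerCharges(mol)
            ch = []
            for a in mol.GetAtoms():
                q = a.GetDoubleProp("_GasteigerCharge")
                ch.append(0.0 if math.isnan(q) or math.isinf(q) else q)
            return {"charges": ch}
        except Exception:
            return {"charges": None}
    if mode == "convert":
        out = []
        for b in req["molblocks"]:
            mol = _mol_from_block(b)
            out.append(None if mol is None
                       else Chem.MolToMolBlock(mol, kekulize=True))
        return {"molblocks": out}
    raise ValueError("unknown mode: %s" % mode)


def main():
    req = json.load(sys.stdin)
    try:
        res = handle(req)
        json.dump({"ok": True, "result": res}, sys.stdout)
    except Exception as exc:  # surfaced as an R condition
        json.dump({"ok": False, "error": str(exc)}, sys.stdout)


if __name__ == "__main__":
    main()
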