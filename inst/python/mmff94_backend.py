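"""MMFF94 backend: atom typing, partial charges, pair vdW parameters and
all-atom local minimization via RDKit. Reads a JSON request from the file
given as argv[1] and writes a JSON response to stdout."""
import json
import sys

import numpy as np
from rdkit import Chem
from rdkit.Chem import AllChem, rdDetermineBonds
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def build(elements, coords, charge=0):
    block = "%d\n\n" % len(elements) + "\n".join(
        "%s %.10f %.10f %.10f" % (e, c[0], c[1], c[2])
        for e, c in zip(elements, coords))
    mol = Chem.MolFromXYZBlock(block)
    if mol is None:
        raise ValueError("could not parse coordinates")
    rdDetermineBonds.DetermineBonds(mol, charge=charge)
    return mol


def combine(mol_i, mol_j):
    mol = Chem.CombineMols(mol_i, mol_j)
    Chem.SanitizeMol(mol)
    return mol


def props_of(mol):
    p = AllChem.MMFFGetMoleculeProperties(mol, mmffVariant="MMFF94")
    if p is None:
        raise ValueError("MMFF94 cannot type this molecule")
    return p


def conformer_coords(mol):
    conf = mol.GetConformer()
    return [list(conf.GetAtomPosition(i)) for i in range(mol.GetNumAtoms())]


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    mode = req["mode"]
    out = {}
    if mode == "check":
        out = {"ok": True, "rdkit": Chem.rdBase.rdkitVersion}
    elif mode == "assign":
        mol = build(req["elements"], req["coords"], req.get("charge", 0))
        p = props_of(mol)
        out["charges"] = [p.GetMMFFPartialCharge(i)
                          for i in range(mol.GetNumAtoms())]
        out["types"] = [p.GetMMFFAtomType(i)
                        for i in range(mol.GetNumAtoms())]
        out["bonds"] = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1]
                        for b in mol.GetBonds()]
    elif mode == "pair_params":
        mol_i = build(req["elements_i"], req["coords_i"])
        mol_j = build(req["elements_j"], req["coords_j"])
        dim = combine(mol_i, mol_j)
        p = props_of(dim)
        ni, nj = mol_i.GetNumAtoms(), mol_j.GetNumAtoms()
        q = [p.GetMMFFPartialCharge(i) for i in range(ni + nj)]
        rstar = np.zeros((ni, nj))
        eps = np.zeros((ni, nj))
        for i in range(ni):
            for j in range(nj):
                pr = p.GetMMFFVdWParams(i, ni + j)
                rstar[i, j], eps[i, j] = pr[2], pr[3]
        out = {"q_i": q[:ni], "q_j": q[ni:],
               "rstar": rstar.tolist(), "eps": eps.tolist()}
    elif mode == "minimize":
        frags = [build(e, c) for e, c in
                 zip(req["elements"], req["coords"])]
        mol = frags[0]
        for f in frags[1:]:
            mol = combine(mol, f)
        p = props_of(mol)
        ff = AllChem.MMFFGetMoleculeForceField(
            mol, p, ignoreInterfragInteractions=False)
        converged = ff.Minimize(maxIts=int(req.get("max_iter", 100000)),
                                forceTol=1e-6, energyTol=1e-12)
        out = {"coords": conformer_coords(mol), "energy": ff.CalcEnergy(),
               "converged": converged == 0}
    elif mode == "energy":
        frags = [build(e, c) for e, c in
                 zip(req["elements"], req["coords"])]
        mol = frags[0]
        for f in frags[1:]:
            mol = combine(mol, f)
        p = props_of(mol)
        ff = AllChem.MMFFGetMoleculeForceField(
            mol, p, ignoreInterfragInteractions=False)
        out = {"energy": ff.CalcEnergy()}
    else:
        raise ValueError("unknown mode: %s" % mode)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
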