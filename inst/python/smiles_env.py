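"""Batch SMILES parser used by the mechstep R package.

Reads a JSON request on stdin and writes a JSON response on stdout.

Request:  {"op": "parse", "smiles": ["CCO", ...]}
      or  {"op": "randomize", "smiles": [...], "n": 5, "seed": 42}

Parsing strips all stereochemistry (molecules are handled as
constitutional isomers) and folds explicit hydrogens into implicit
H counts, so atoms are heavy atoms only.
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

BOND_SYMBOL = {1.0: "-", 2.0: "=", 3.0: "#", 1.5: ":"}


def parse_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"error": "SMILES parse failure"}
    Chem.RemoveStereochemistry(mol)
    mol = Chem.RemoveHs(mol)
    atoms = []
    elements = {}
    for atom in mol.GetAtoms():
        sym = atom.GetSymbol()
        n_h = atom.GetTotalNumHs()
        atoms.append(
            {
                "element": sym,
                "charge": atom.GetFormalCharge(),
                "n_h": n_h,
                "aromatic": bool(atom.GetIsAromatic()),
            }
        )
        elements[sym] = elements.get(sym, 0) + 1
        if n_h:
            elements["H"] = elements.get("H", 0) + n_h
    bonds = []
    for bond in mol.GetBonds():
        order = BOND_SYMBOL.get(bond.GetBondTypeAsDouble())
        if order is None:
            return {"error": "unsupported bond order %s" % bond.GetBondType()}
        bonds.append(
            {
                "a": bond.GetBeginAtomIdx() + 1,  # 1-based for R
                "b": bond.GetEndAtomIdx() + 1,
                "order": order,
            }
        )
    return {
        "canonical": Chem.MolToSmiles(mol),
        "net_charge": Chem.GetFormalCharge(mol),
        "element_counts": elements,
        "atoms": atoms,
        "bonds": bonds,
    }


def randomize_one(smi, n, seed):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"error": "SMILES parse failure"}
    Chem.RemoveStereochemistry(mol)
    mol = Chem.RemoveHs(mol)
    return {"variants": list(Chem.MolToRandomSmilesVect(mol, n, randomSeed=seed))}


def main():
    req = json.load(sys.stdin)
    op = req.get("op", "parse")
    if op == "parse":
        out = [parse_one(s) for s in req["smiles"]]
    elif op == "randomize":
        n = int(req.get("n", 5))
        seed = int(req.get("seed", 1))
        out = [randomize_one(s, n, seed + i) for i, s in enumerate(req["smiles"])]
    else:
        raise SystemExit("unknown op: %s" % op)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
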