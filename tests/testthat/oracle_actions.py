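"""Independent brute-force action-space oracle used by the test suite.

For a molecule, attempts every conceivable single graph edit directly with
RDKit (all atom/element/order triples, all atom-pair bond changes, all bond
decrements), keeps the sanitizable products, and applies the published
heuristics (no edits on aromatic bonds, no bond formation between two
in-ring atoms, ring-size whitelist, fragment cleanup rule). Written
independently of the package's enumeration (which builds candidate edit
lists in R); agreement is the oracle-equivalence test.

Usage: python oracle_actions.py '<json>' with keys smiles, elements,
ring_sizes. Prints a JSON object {atom: [...], bond: [...], removal: [...]}.
"""
import itertools
import json
import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")

BOND = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE, 3: Chem.BondType.TRIPLE}
ORDER = {v: k for k, v in BOND.items()}


def free_valence(atom):
    return atom.GetNumImplicitHs() + atom.GetNumExplicitHs()


def sanitized_smiles(rw):
    try:
        Chem.SanitizeMol(rw)
    except Exception:
        return None
    return Chem.MolToSmiles(rw)


def atom_additions(mol, elements):
    out = set()
    if mol is None:
        for el in elements:
            rw = Chem.RWMol()
            rw.AddAtom(Chem.Atom(el))
            smi = sanitized_smiles(rw)
            if smi:
                out.add(smi)
        return out
    for atom in mol.GetAtoms():
        for el in elements:
            for order in (1, 2, 3):
                if order > free_valence(atom):
                    continue
                rw = Chem.RWMol(mol)
                Chem.Kekulize(rw, clearAromaticFlags=True)
                idx = rw.AddAtom(Chem.Atom(el))
                rw.AddBond(atom.GetIdx(), idx, BOND[order])
                smi = sanitized_smiles(rw)
                if smi:
                    out.add(smi)
    return out


def bond_additions(mol, ring_sizes):
    out = set()
    if mol is None:
        return out
    for a1, a2 in itertools.combinations(mol.GetAtoms(), 2):
        if free_valence(a1) == 0 or free_valence(a2) == 0:
            continue
        if a1.IsInRing() and a2.IsInRing():
            continue
        i, j = a1.GetIdx(), a2.GetIdx()
        bond = mol.GetBondBetweenAtoms(i, j)
        if bond is not None and bond.GetBondType() not in ORDER:
            continue  # aromatic bond: never modified
        cur = ORDER[bond.GetBondType()] if bond is not None else 0
        deltas = (1, 2) if cur else (1, 2, 3)
        for delta in deltas:
            new = cur + delta
            if new > 3 or delta > min(free_valence(a1), free_valence(a2)):
                continue
            rw = Chem.RWMol(mol)
            Chem.Kekulize(rw, clearAromaticFlags=True)
            if bond is None:
                rw.AddBond(i, j, BOND[new])
            else:
                rw.GetBondBetweenAtoms(i, j).SetBondType(BOND[new])
            smi = sanitized_smiles(rw)
            if not smi:
                continue
            if bond is None:
                # re-apply the edit to inspect the rings through the new bond
                rw2 = Chem.RWMol(mol)
                Chem.Kekulize(rw2, clearAromaticFlags=True)
                rw2.AddBond(i, j, BOND[new])
                Chem.SanitizeMol(rw2)
                m2 = rw2.GetMol()
                nb = m2.GetBondBetweenAtoms(i, j)
                sizes = [len(r) for r in m2.GetRingInfo().BondRings()
                         if nb.GetIdx() in r]
                if sizes and any(s not in ring_sizes for s in sizes):
                    continue
            out.add(smi)
    return out


def bond_removals(mol):
    out = set()
    if mol is None:
        return out
    for bond in mol.GetBonds():
        if bond.GetBondType() not in ORDER:
            continue
        cur = ORDER[bond.GetBondType()]
        i, j = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        for new in range(cur):
            rw = Chem.RWMol(mol)
            Chem.Kekulize(rw, clearAromaticFlags=True)
            if new > 0:
                rw.GetBondBetweenAtoms(i, j).SetBondType(BOND[new])
            else:
                rw.RemoveBond(i, j)
                frags = Chem.GetMolFrags(rw)
                if len(frags) > 2:
                    continue
                if len(frags) == 2:
                    sizes = sorted(len(f) for f in frags)
                    if sizes[0] != 1 or sizes[1] < 2:
                        continue
                    rw.RemoveAtom(min(frags, key=len)[0])
            smi = sanitized_smiles(rw)
            if smi:
                out.add(smi)
    return out


def enumerate_one(smiles, elements, ring_sizes):
    mol = Chem.MolFromSmiles(smiles) if smiles else None
    return {
        "atom": sorted(atom_additions(mol, elements)),
        "bond": sorted(bond_additions(mol, ring_sizes)),
        "removal": sorted(bond_removals(mol)),
    }


def main():
    req = json.loads(sys.argv[1])
    ring_sizes = set(req.get("ring_sizes", [5, 6, 7]))
    smiles = req["smiles"]
    if isinstance(smiles, list):
        print(json.dumps([enumerate_one(s, req["elements"], ring_sizes)
                          for s in smiles]))
    else:
        print(json.dumps(enumerate_one(smiles, req["elements"], ring_sizes)))


if __name__ == "__main__":
    main()
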