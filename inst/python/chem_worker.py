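"""JSON-lines chemistry worker backing the moldqn R package.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout. Supplies RDKit primitives only (parsing/sanitization, single graph
edits, descriptors, Morgan fingerprints); all decision logic lives in R.
"""
import json
import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import AllChem, Descriptors, QED

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

BOND = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE, 3: Chem.BondType.TRIPLE}
ORDER = {v: k for k, v in BOND.items()}


def _mol(smiles):
    if not smiles:
        return None
    m = Chem.MolFromSmiles(smiles)
    if m is None:
        raise ValueError("unparsable SMILES: %r" % smiles)
    return m


def op_parse(req):
    smiles = req["smiles"]
    if not smiles:
        return {"smiles": "", "natoms": 0, "atoms": [], "bonds": [], "had_stereo": False}
    m = _mol(smiles)
    had_stereo = any(a.GetChiralTag() != Chem.ChiralType.CHI_UNSPECIFIED for a in m.GetAtoms()) or any(
        b.GetStereo() != Chem.BondStereo.STEREONONE for b in m.GetBonds())
    if had_stereo:
        Chem.RemoveStereochemistry(m)
    # Re-parse the canonical form so the reported atom indices match a later
    # MolFromSmiles() on the canonical SMILES (atom order follows the SMILES
    # text, so tables built from a non-canonical input would not transfer).
    m = _mol(Chem.MolToSmiles(m))
    atoms = [{"i": a.GetIdx(), "el": a.GetSymbol(),
              "fv": a.GetNumImplicitHs() + a.GetNumExplicitHs(),
              "ring": a.IsInRing()} for a in m.GetAtoms()]
    bonds = [{"a": b.GetBeginAtomIdx(), "b": b.GetEndAtomIdx(),
              "order": ORDER.get(b.GetBondType(), 0),
              "arom": b.GetBondType() == Chem.BondType.AROMATIC,
              "ring": b.IsInRing()} for b in m.GetBonds()]
    return {"smiles": Chem.MolToSmiles(m), "natoms": m.GetNumAtoms(),
            "atoms": atoms, "bonds": bonds, "had_stereo": had_stereo}


def _apply_edit(mol, edit):
    """Apply one graph edit; return (ok, smiles, ring_sizes_of_new_bond)."""
    rw = Chem.RWMol(mol)
    Chem.Kekulize(rw, clearAromaticFlags=True)
    op = edit["op"]
    new_bond = None
    if op == "addatom":
        idx = rw.AddAtom(Chem.Atom(edit["el"]))
        rw.AddBond(int(edit["atom"]), idx, BOND[int(edit["order"])])
    elif op == "bond":
        a, b, order = int(edit["a"]), int(edit["b"]), int(edit["order"])
        bond = rw.GetBondBetweenAtoms(a, b)
        if order == 0:
            rw.RemoveBond(a, b)
            frags = Chem.GetMolFrags(rw)
            if len(frags) == 2:
                sizes = sorted(len(f) for f in frags)
                if sizes[0] != 1 or sizes[1] < 2:
                    return False, None, None
                lone = min(frags, key=len)[0]
                rw.RemoveAtom(lone)
            elif len(frags) > 2:
                return False, None, None
        elif bond is None:
            rw.AddBond(a, b, BOND[order])
            new_bond = (a, b)
        else:
            bond.SetBondType(BOND[order])
    else:
        raise ValueError("unknown edit op: %r" % op)
    try:
        Chem.SanitizeMol(rw)
    except Exception:
        return False, None, None
    ring_sizes = []
    if new_bond is not None:
        m2 = rw.GetMol()
        nb = m2.GetBondBetweenAtoms(*new_bond)
        ri = m2.GetRingInfo()
        ring_sizes = [len(r) for r in ri.BondRings() if nb.GetIdx() in r]
    return True, Chem.MolToSmiles(rw), ring_sizes


def op_edits(req):
    mol = _mol(req["smiles"])
    out = []
    for edit in req["edits"]:
        ok, smi, rings = _apply_edit(mol, edit)
        out.append({"ok": ok, "smiles": smi, "rings": rings})
    return {"results": out}


def op_seeds(req):
    out = []
    for el in req["elements"]:
        rw = Chem.RWMol()
        rw.AddAtom(Chem.Atom(el))
        try:
            Chem.SanitizeMol(rw)
            out.append(Chem.MolToSmiles(rw))
        except Exception:
            out.append(None)
    return {"smiles": out}


def _largest_ring(m):
    return max((len(r) for r in m.GetRingInfo().AtomRings()), default=0)


def op_props(req):
    fields = req["fields"]
    out = {f: [] for f in fields}
    for smi in req["smiles"]:
        m = _mol(smi)
        for f in fields:
            if m is None:
                out[f].append(0.0)
            elif f == "logp":
                out[f].append(Descriptors.MolLogP(m))
            elif f == "sa":
                out[f].append(sascorer.calculateScore(m))
            elif f == "qed":
                out[f].append(QED.qed(m))
            elif f == "maxring":
                out[f].append(_largest_ring(m))
            elif f == "nring_gt6":
                out[f].append(sum(1 for r in m.GetRingInfo().AtomRings() if len(r) > 6))
            elif f == "natoms":
                out[f].append(m.GetNumAtoms())
            else:
                raise ValueError("unknown property field: %r" % f)
    return {"props": out}


def op_fps(req):
    radius = int(req.get("radius", 3))
    nbits = int(req.get("nbits", 2048))
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append([])
        else:
            out.append(sorted(gen.GetFingerprint(m).GetOnBits()))
    return {"onbits": out}


OPS = {"parse": op_parse, "edits": op_edits, "seeds": op_seeds,
       "props": op_props, "fps": op_fps,
       "hello": lambda req: {"rdkit": Chem.rdBase.rdkitVersion}}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        req = json.loads(line)
        try:
            resp = OPS[req["op"]](req)
            resp["ok"] = True
        except Exception as exc:  # report, never die mid-session
            resp = {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}
        resp["id"] = req.get("id")
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
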