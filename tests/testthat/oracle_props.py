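"""Independent descriptor oracle for the test suite.

Computes, directly with RDKit (no package code involved): the penalized
logP chain logP - SA - max(0, largest_ring - 6), QED, Morgan on-bit lists,
and Tanimoto similarities via RDKit's own fingerprint similarity (the
package computes Tanimoto by explicit set arithmetic in R, so this is a
genuinely distinct route).

Usage: python oracle_props.py '<json>' with keys smiles (list) and
optionally ref (similarity reference). Prints JSON columns.
"""
import json
import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import AllChem, DataStructs, Descriptors, QED

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def main():
    req = json.loads(sys.argv[1])
    mols = [Chem.MolFromSmiles(s) for s in req["smiles"]]
    gen2 = AllChem.GetMorganGenerator(radius=2, fpSize=2048)
    gen3 = AllChem.GetMorganGenerator(radius=3, fpSize=2048)
    out = {
        "logp": [Descriptors.MolLogP(m) for m in mols],
        "sa": [sascorer.calculateScore(m) for m in mols],
        "qed": [QED.qed(m) for m in mols],
        "plogp": [],
        "onbits3": [sorted(gen3.GetFingerprint(m).GetOnBits()) for m in mols],
    }
    for m in mols:
        largest = max((len(r) for r in m.GetRingInfo().AtomRings()), default=0)
        out["plogp"].append(Descriptors.MolLogP(m) - sascorer.calculateScore(m)
                            - max(0, largest - 6))
    if req.get("ref"):
        ref = gen2.GetFingerprint(Chem.MolFromSmiles(req["ref"]))
        out["tanimoto"] = [DataStructs.TanimotoSimilarity(ref, gen2.GetFingerprint(m))
                           for m in mols]
    print(json.dumps(out))


if __name__ == "__main__":
    main()
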