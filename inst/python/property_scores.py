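#!/usr/bin/env python
"""Batched molecular property scoring (RDKit backend).

Reads SMILES, one per line, on stdin; writes one line per input to stdout:
<line-number>\t<score> (score is "NA" when the SMILES cannot be parsed).

Properties:
  qed      quantitative estimate of drug-likeness, in [0, 1]
  plogp    penalized logP: Crippen logP - synthetic accessibility
           - max(0, largest ring size - 6)   (unnormalized convention)
  plogp_z  the z-scored variant of plogp (ZINC250k moments)
"""
import sys
import os
import argparse

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import QED, Crippen

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

# ZINC250k moments commonly used for the normalized penalized-logP variant
LOGP_MEAN, LOGP_SD = 2.4570953396190123, 1.434324401111988
SA_MEAN, SA_SD = 3.0525811293166134, 0.8335207024513095
CYCLE_MEAN, CYCLE_SD = 0.0485696876403053, 0.2860212110245455


def cycle_penalty(mol):
    sizes = [len(r) for r in mol.GetRingInfo().AtomRings()]
    longest = max(sizes) if sizes else 0
    return max(0, longest - 6)


def score(mol, prop):
    if prop == "qed":
        return QED.qed(mol)
    logp = Crippen.MolLogP(mol)
    sa = sascorer.calculateScore(mol)
    cyc = cycle_penalty(mol)
    if prop == "plogp":
        return logp - sa - cyc
    if prop == "plogp_z":
        return ((logp - LOGP_MEAN) / LOGP_SD
                - (sa - SA_MEAN) / SA_SD
                - (cyc - CYCLE_MEAN) / CYCLE_SD)
    raise ValueError("unknown property: %s" % prop)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("property", choices=["qed", "plogp", "plogp_z"])
    args = ap.parse_args()
    for i, line in enumerate(sys.stdin, start=1):
        smi = line.strip()
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None:
            sys.stdout.write("%d\tNA\n" % i)
        else:
            sys.stdout.write("%d\t%.12g\n" % (i, score(mol, args.property)))


if __name__ == "__main__":
    main()
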