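"""Conformer embedding helper: seeded ETKDG distance-geometry trials,
MMFF94 minimization, energy-window filter and RMSD deduplication.

Usage: python embed_conformers.py SMILES WINDOW RMSD MAXCONF SEED
Writes a multi-record SDF to stdout; each record carries an
<energy_kcal> property (MMFF94, absolute). Exits non-zero on failure.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem import rdMolAlign, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def main():
    smi, window, rmsd_thr, maxconf, seed = (
        sys.argv[1],
        float(sys.argv[2]),
        float(sys.argv[3]),
        int(sys.argv[4]),
        int(sys.argv[5]),
    )
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        sys.exit(2)
    mol = Chem.AddHs(mol)

    # trial count scales with flexibility: min 20, max 300
    n_rot = rdMolDescriptors.CalcNumRotatableBonds(mol)
    n_trials = min(300, max(20, 30 * n_rot))

    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.useRandomCoords = False
    cids = AllChem.EmbedMultipleConfs(mol, numConfs=n_trials, params=params)
    if len(cids) == 0:
        # fall back to random-coordinate initialization before giving up
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=n_trials, params=params)
    if len(cids) == 0:
        sys.exit(3)

    if AllChem.MMFFHasAllMoleculeParams(mol):
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=1000)
    else:
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=1000)
    energies = [e for (_conv, e) in res]

    order = sorted(range(len(cids)), key=lambda i: (energies[i], i))
    emin = energies[order[0]]

    heavy = [a.GetIdx() for a in mol.GetAtoms() if a.GetAtomicNum() > 1]
    amap = [(i, i) for i in heavy]
    kept = []
    for i in order:
        if energies[i] > emin + window:
            break
        dup = False
        for j in kept:
            r = rdMolAlign.GetBestRMS(mol, mol, prbId=cids[i], refId=cids[j],
                                      map=[amap])
            if r < rmsd_thr:
                dup = True
                break
        if not dup:
            kept.append(i)
        if len(kept) >= maxconf:
            break

    w = Chem.SDWriter(sys.stdout)
    w.SetKekulize(True)
    for i in kept:
        mol.SetProp("_Name", "conf_%d" % i)
        mol.SetProp("energy_kcal", "%.6f" % energies[i])
        w.write(mol, confId=cids[i])
    w.close()


if __name__ == "__main__":
    main()
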