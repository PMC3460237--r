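"""Deterministic 3D embedding helper: SDF in, SDF out (heavy atoms only).

Usage: python embed3d.py <in.sdf> <out.sdf> <seed>
Embeds each record with ETKDGv3 at the given random seed so repeated runs
give identical coordinates. Heavy-atom order of the input is preserved.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main():
    inp, out, seed = sys.argv[1], sys.argv[2], int(sys.argv[3])
    writer = Chem.SDWriter(out)
    for mol in Chem.SDMolSupplier(inp, removeHs=True):
        if mol is None:
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = seed
        if AllChem.EmbedMolecule(molh, params) != 0:
            continue
        writer.write(Chem.RemoveHs(molh))
    writer.close()


if __name__ == "__main__":
    main()
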