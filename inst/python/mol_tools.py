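"""RDKit bridge for dtafuse.

Called by the R package through system2(); all I/O is JSON so the R side
never links against RDKit directly.

Commands:
    parse    <smiles_file> <out_json>   one SMILES per line -> molecule records
    tanimoto <smiles_file> <out_json>   one SMILES per line -> ECFP4/2048
                                        Tanimoto similarity matrix
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

BOND_TYPES = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}

CHI_TAGS = {
    Chem.ChiralType.CHI_UNSPECIFIED: "none",
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "cw",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "ccw",
}

STEREO = {
    Chem.BondStereo.STEREONONE: "none",
    Chem.BondStereo.STEREOZ: "z",
    Chem.BondStereo.STEREOE: "e",
    Chem.BondStereo.STEREOCIS: "cis",
    Chem.BondStereo.STEREOTRANS: "trans",
}


def mol_record(smiles):
    if not smiles:
        return {"smiles": smiles, "error": "empty SMILES string"}
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"smiles": smiles, "error": "unparsable SMILES"}
    atoms = []
    for a in mol.GetAtoms():
        atoms.append(
            {
                "element": a.GetSymbol(),
                "degree": a.GetDegree(),
                "aromatic": bool(a.GetIsAromatic()),
                "charge": a.GetFormalCharge(),
                "chirality": CHI_TAGS.get(a.GetChiralTag(), "other"),
                "in_ring": bool(a.IsInRing()),
            }
        )
    bonds = []
    for b in mol.GetBonds():
        bonds.append(
            {
                "i": b.GetBeginAtomIdx(),
                "j": b.GetEndAtomIdx(),
                "type": BOND_TYPES.get(b.GetBondType(), "other"),
                "stereo": STEREO.get(b.GetStereo(), "other"),
                "in_ring": bool(b.IsInRing()),
            }
        )
    ri = mol.GetRingInfo()
    return {
        "smiles": smiles,
        "canonical": Chem.MolToSmiles(mol),
        "atoms": atoms,
        "bonds": bonds,
        "ring_atoms": [list(r) for r in ri.AtomRings()],
        "ring_bonds": [list(r) for r in ri.BondRings()],
    }


def cmd_parse(infile, outfile):
    with open(infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    records = [mol_record(s) for s in smiles]
    with open(outfile, "w") as fh:
        json.dump(records, fh)


def cmd_tanimoto(infile, outfile):
    from rdkit.Chem import AllChem
    from rdkit import DataStructs

    with open(infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    fps = []
    for s in smiles:
        mol = Chem.MolFromSmiles(s)
        if mol is None:
            json.dump({"error": "unparsable SMILES: " + s}, open(outfile, "w"))
            return
        fps.append(AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=2048))
    n = len(fps)
    sim = [[DataStructs.TanimotoSimilarity(fps[i], fps[j]) for j in range(n)]
           for i in range(n)]
    with open(outfile, "w") as fh:
        json.dump({"similarity": sim}, fh)


def main(argv):
    if len(argv) != 4 or argv[1] not in {"parse", "tanimoto"}:
        sys.stderr.write(__doc__)
        return 2
    if argv[1] == "parse":
        cmd_parse(argv[2], argv[3])
    else:
        cmd_tanimoto(argv[2], argv[3])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
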