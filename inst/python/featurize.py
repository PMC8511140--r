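"""Molecular perception backend for the ccgnet R package.

Reads a JSON job from argv[1], writes a JSON result to argv[2].

Jobs:
  {"op": "canonicalize", "smiles": ["CCO", ...]}
  {"op": "featurize", "seed": 7,
   "records": [{"id": "m1", "smiles": "CCO"} | {"id": "m2", "molblock": "..."}]}

All perception (aromaticity, CIP chirality, hybridization, pharmacophore
donor/acceptor SMARTS, ETKDG conformers, Gasteiger charges, TPSA, FreeSASA,
grid molecular volume, rotatable bonds) is delegated to RDKit; geometry- and
graph-derived quantities are computed downstream in R.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, Lipinski, rdFreeSASA

RDLogger.DisableLog("rdApp.*")

ALLOWED = {"C", "H", "O", "N", "P", "S", "Cl", "Br", "I", "F", "Si", "B"}
BOND_NAMES = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}
HYB_NAMES = {"SP": "SP", "SP2": "SP2", "SP3": "SP3", "S": "S"}


def canonical(smi):
    mol = Chem.MolFromSmiles(smi)
    return None if mol is None else Chem.MolToSmiles(mol)


def inspect(smi):
    """Composition-level facts used by dataset screening; no 3D embedding."""
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "parse error: unparseable SMILES %r" % smi}
    return {
        "ok": True,
        "canonical_smiles": Chem.MolToSmiles(mol),
        "mw": Descriptors.MolWt(mol),
        "net_charge": Chem.GetFormalCharge(mol),
        "elements": sorted({a.GetSymbol() for a in mol.GetAtoms()} | {"H"}
                           if any(a.GetTotalNumHs() for a in mol.GetAtoms())
                           else {a.GetSymbol() for a in mol.GetAtoms()}),
        "n_fragments": len(Chem.GetMolFrags(mol)),
    }


def parse_record(rec):
    if rec.get("smiles") is not None:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            raise ValueError("parse error: unparseable SMILES %r" % rec["smiles"])
        return mol, False
    if rec.get("molblock") is not None:
        mol = Chem.MolFromMolBlock(rec["molblock"], removeHs=False)
        if mol is None:
            raise ValueError("parse error: unparseable MOL/SDF block")
        has3d = mol.GetNumConformers() > 0 and mol.GetConformer().Is3D()
        return mol, has3d
    raise ValueError("parse error: record carries neither smiles nor molblock")


def embed(molh, seed):
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(molh, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(molh, params) != 0:
            raise ValueError("embedding error: 3D conformer generation failed")
    try:
        if AllChem.MMFFOptimizeMolecule(molh, maxIters=500) == -1:
            AllChem.UFFOptimizeMolecule(molh, maxIters=500)
    except Exception:
        pass


def spiro_atoms(mol):
    """Atoms shared by exactly one atom of two rings (classic spiro centre)."""
    rings = [set(r) for r in mol.GetRingInfo().AtomRings()]
    out = set()
    for i in range(len(rings)):
        for j in range(i + 1, len(rings)):
            common = rings[i] & rings[j]
            if len(common) == 1:
                out |= common
    return out


def featurize_one(rec, seed):
    mol, has3d = parse_record(rec)
    if len(Chem.GetMolFrags(mol)) != 1:
        raise ValueError("parse error: record is not a single connected molecule")
    mol_noh = Chem.RemoveHs(mol)
    for atom in mol_noh.GetAtoms():
        if atom.GetSymbol() not in ALLOWED:
            raise ValueError("element error: %s outside supported set" % atom.GetSymbol())

    Chem.AssignStereochemistry(mol_noh, cleanIt=True, force=True)
    n_heavy = mol_noh.GetNumAtoms()
    cip = ["None"] * n_heavy
    for atom in mol_noh.GetAtoms():
        if atom.HasProp("_CIPCode"):
            cip[atom.GetIdx()] = atom.GetProp("_CIPCode")
    donors = {i for (i,) in mol_noh.GetSubstructMatches(Lipinski.HDonorSmarts)}
    acceptors = {i for (i,) in mol_noh.GetSubstructMatches(Lipinski.HAcceptorSmarts)}
    spiro = spiro_atoms(mol_noh)

    if has3d:
        molh = Chem.AddHs(mol, addCoords=True)
    else:
        molh = Chem.AddHs(mol_noh)
        embed(molh, seed)
    Chem.AssignStereochemistry(molh, cleanIt=True, force=True)
    AllChem.ComputeGasteigerCharges(molh)
    pt = Chem.GetPeriodicTable()

    atoms = {k: [] for k in (
        "symbol", "formal_charge", "chirality", "hybridization", "is_chiral",
        "is_spiro", "is_cyclic", "is_aromatic", "is_acceptor", "is_donor",
        "explicit_valence", "implicit_valence", "degree", "total_h",
        "atomic_number", "vdw_radius", "gasteiger")}
    # AddHs appends hydrogens after the heavy atoms, so heavy index i in
    # mol_noh is index i in molh; heavy-atom annotations map through directly.
    for atom in molh.GetAtoms():
        idx = atom.GetIdx()
        heavy = idx < n_heavy
        atoms["symbol"].append(atom.GetSymbol())
        atoms["formal_charge"].append(atom.GetFormalCharge())
        atoms["chirality"].append(cip[idx] if heavy else "None")
        hyb = HYB_NAMES.get(str(atom.GetHybridization()), "")
        if atom.GetAtomicNum() == 1:
            hyb = "S"
        atoms["hybridization"].append(hyb)
        atoms["is_chiral"].append(int(heavy and cip[idx] != "None"))
        atoms["is_spiro"].append(int(heavy and idx in spiro))
        atoms["is_cyclic"].append(int(atom.IsInRing()))
        atoms["is_aromatic"].append(int(atom.GetIsAromatic()))
        atoms["is_acceptor"].append(int(heavy and idx in acceptors))
        atoms["is_donor"].append(int(heavy and idx in donors))
        atoms["explicit_valence"].append(atom.GetExplicitValence())
        atoms["implicit_valence"].append(atom.GetImplicitValence())
        atoms["degree"].append(atom.GetDegree())
        atoms["total_h"].append(sum(1 for nb in atom.GetNeighbors()
                                    if nb.GetAtomicNum() == 1))
        atoms["atomic_number"].append(atom.GetAtomicNum())
        atoms["vdw_radius"].append(pt.GetRvdw(atom.GetAtomicNum()))
        charge = atom.GetDoubleProp("_GasteigerCharge")
        atoms["gasteiger"].append(charge if charge == charge else 0.0)

    bonds = {"i": [], "j": [], "type": []}
    for bond in molh.GetBonds():
        btype = BOND_NAMES.get(bond.GetBondType())
        if btype is None:
            raise ValueError("unsupported bond type: %s" % bond.GetBondType())
        bonds["i"].append(bond.GetBeginAtomIdx() + 1)  # 1-based for R
        bonds["j"].append(bond.GetEndAtomIdx() + 1)
        bonds["type"].append(btype)

    conf = molh.GetConformer()
    coords = [[conf.GetAtomPosition(k).x, conf.GetAtomPosition(k).y,
               conf.GetAtomPosition(k).z] for k in range(molh.GetNumAtoms())]

    radii = rdFreeSASA.classifyAtoms(molh)
    sasa = rdFreeSASA.CalcSASA(molh, radii)
    return {
        "ok": True,
        "id": rec.get("id"),
        "canonical_smiles": Chem.MolToSmiles(mol_noh),
        "net_charge": Chem.GetFormalCharge(mol_noh),
        "mw": Descriptors.MolWt(mol_noh),
        "atoms": atoms,
        "bonds": bonds,
        "coords": coords,
        "mol_props": {
            "tpsa": Descriptors.TPSA(mol_noh),
            "sasa": sasa,
            "volume": AllChem.ComputeMolVolume(molh),
            "rbn": Lipinski.NumRotatableBonds(mol_noh),
        },
    }


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)
    if job.get("op") == "canonicalize":
        out = {"canonical": [canonical(s) for s in job["smiles"]]}
    elif job.get("op") == "inspect":
        out = {"inspect": [inspect(s) for s in job["smiles"]]}
    else:
        seed = job.get("seed", 2024)
        mols = []
        for rec in job["records"]:
            try:
                mols.append(featurize_one(rec, seed))
            except ValueError as exc:
                mols.append({"ok": False, "id": rec.get("id"), "error": str(exc)})
        out = {"molecules": mols}
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
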