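"""Line-oriented JSON backend for confabR.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout. Delegates MMFF94 parameterisation/evaluation, SMARTS matching and
aromaticity/ring perception to RDKit. Atom order is never changed; all atom
indices on the wire are 0-based.

Energy split: the "variable" energy is the torsion + van der Waals +
electrostatic sum (the terms that change under torsion driving); the
"constant" part (bond stretch, angle bend, stretch-bend, out-of-plane) is
total - variable at any geometry of the same torsion-driven molecule.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Geometry import Point3D

RDLogger.DisableLog("rdApp.*")

MOLS = {}
NEXT_ID = [1]


def mol_from_sdf(text, sanitize=True):
    supp = Chem.SDMolSupplier()
    supp.SetData(text, removeHs=False, sanitize=sanitize)
    mols = [m for m in supp]
    return mols


def ff_for(mol, which, variant):
    props = AllChem.MMFFGetMoleculeProperties(mol, mmffVariant=variant)
    if props is None:
        return None
    if which == "variable":
        props.SetMMFFBondTerm(False)
        props.SetMMFFAngleTerm(False)
        props.SetMMFFStretchBendTerm(False)
        props.SetMMFFOopTerm(False)
    return AllChem.MMFFGetMoleculeForceField(mol, props)


def set_coords(mol, flat):
    conf = mol.GetConformer()
    n = mol.GetNumAtoms()
    for i in range(n):
        conf.SetAtomPosition(i, Point3D(flat[3 * i], flat[3 * i + 1], flat[3 * i + 2]))


def op_load(req):
    mols = mol_from_sdf(req["sdf"])
    if len(mols) != 1 or mols[0] is None:
        return {"error": "could not parse SDF record"}
    mol = mols[0]
    variant = req.get("variant", "MMFF94")
    props = AllChem.MMFFGetMoleculeProperties(mol, mmffVariant=variant)
    typed = props is not None
    out = {"typed": typed, "natoms": mol.GetNumAtoms()}
    if typed:
        ff_tot = ff_for(mol, "total", variant)
        ff_var = ff_for(mol, "variable", variant)
        tot = ff_tot.CalcEnergy()
        var = ff_var.CalcEnergy()
        out["total"] = tot
        out["variable"] = var
        out["constant"] = tot - var
    mid = NEXT_ID[0]
    NEXT_ID[0] += 1
    MOLS[mid] = (mol, variant)
    out["id"] = mid
    return out


def op_energies(req):
    mol, variant = MOLS[req["id"]]
    ff_tot = ff_for(mol, "total", variant)
    ff_var = ff_for(mol, "variable", variant)
    totals, variables = [], []
    for flat in req["coords"]:
        pos = [float(x) for x in flat]
        totals.append(ff_tot.CalcEnergy(pos))
        variables.append(ff_var.CalcEnergy(pos))
    return {"total": totals, "variable": variables}


def op_smarts(req):
    mol, _ = MOLS[req["id"]]
    res = []
    for patt in req["patterns"]:
        q = Chem.MolFromSmarts(patt)
        if q is None:
            res.append({"valid": False})
            continue
        matches = mol.GetSubstructMatches(q, uniquify=False, maxMatches=10000)
        res.append({
            "valid": True,
            "natoms": q.GetNumAtoms(),
            "matches": [list(m) for m in matches],
        })
    return {"patterns": res}


def op_patinfo(req):
    res = []
    for patt in req["patterns"]:
        q = Chem.MolFromSmarts(patt)
        res.append({"valid": q is not None,
                    "natoms": 0 if q is None else q.GetNumAtoms()})
    return {"patterns": res}


def op_perceive(req):
    mols = mol_from_sdf(req["sdf"])
    if len(mols) != 1 or mols[0] is None:
        return {"error": "could not parse SDF record"}
    mol = mols[0]
    arom_atoms = [a.GetIdx() for a in mol.GetAtoms() if a.GetIsAromatic()]
    ri = mol.GetRingInfo()
    ring_atoms = [a.GetIdx() for a in mol.GetAtoms() if ri.NumAtomRings(a.GetIdx()) > 0]
    arom_bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()]
                  for b in mol.GetBonds() if b.GetIsAromatic()]
    return {"aromatic_atoms": arom_atoms, "ring_atoms": ring_atoms,
            "aromatic_bonds": arom_bonds}


def op_release(req):
    MOLS.pop(req["id"], None)
    return {"ok": True}


OPS = {
    "ping": lambda req: {"pong": True},
    "load": op_load,
    "energies": op_energies,
    "smarts": op_smarts,
    "patinfo": op_patinfo,
    "perceive": op_perceive,
    "release": op_release,
}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("op") == "shutdown":
                break
            out = OPS[req["op"]](req)
        except Exception as exc:  # report, never die mid-session
            out = {"error": "%s: %s" % (type(exc).__name__, exc)}
        sys.stdout.write(json.dumps(out) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
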