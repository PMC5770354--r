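"""RDKit bridge for the autoqsar R package.

Batch subprocess interface: every invocation reads one input file, writes
one CSV output file, and exits. Keeping all cheminformatics in a single
toolkit guarantees one canonical-SMILES dialect across curation,
featurization and prediction.

Usage:
    python chem_bridge.py version            OUTFILE
    python chem_bridge.py canonicalize INFILE OUTFILE
    python chem_bridge.py descriptors  INFILE OUTFILE
    python chem_bridge.py fingerprints INFILE OUTFILE ARGS_JSON
    python chem_bridge.py parse_sdf    INFILE OUTFILE

INFILE for canonicalize/descriptors/fingerprints: TSV lines "id<TAB>smiles".
ARGS_JSON: {"kind": ..., "n_bits": int, "radius": int}.
"""

import csv
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, MACCSkeys, rdFingerprintGenerator
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Avalon import pyAvalonTools
import rdkit

RDLogger.DisableLog("rdApp.*")

UNCHARGER = rdMolStandardize.Uncharger()


def read_tsv(path):
    rows = []
    with open(path, encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            rows.append((ident, smiles))
    return rows


def largest_organic_fragment(mol):
    """Parent extraction: the fragment with the most heavy atoms among
    those containing carbon. Ties: more atoms overall, then canonical
    SMILES order (deterministic)."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    organic = [f for f in frags
               if any(a.GetAtomicNum() == 6 for a in f.GetAtoms())]
    if not organic:
        return None
    keyed = sorted(
        organic,
        key=lambda f: (-f.GetNumHeavyAtoms(), -f.GetNumAtoms(),
                       Chem.MolToSmiles(f)))
    return keyed[0]


def canonicalize(rows, out):
    w = csv.writer(out)
    w.writerow(["compound_id", "canonical_smiles", "status", "reason"])
    for ident, smiles in rows:
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            w.writerow([ident, "", "rejected", "invalid_structure"])
            continue
        parent = largest_organic_fragment(mol)
        if parent is None:
            w.writerow([ident, "", "rejected", "inorganic_only"])
            continue
        try:
            Chem.SanitizeMol(parent)
            # salts often leave a charged parent; neutralize it so salt
            # forms and free bases collapse onto one canonical structure
            parent = UNCHARGER.uncharge(parent)
            can = Chem.MolToSmiles(parent)
        except Exception:
            w.writerow([ident, "", "rejected", "invalid_structure"])
            continue
        w.writerow([ident, can, "ok", ""])


def descriptors(rows, out):
    names = [n for n, _ in Descriptors.descList]
    w = csv.writer(out)
    w.writerow(["compound_id", "status"] + names)
    for ident, smiles in rows:
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            w.writerow([ident, "invalid_structure"] + [""] * len(names))
            continue
        try:
            vals = Descriptors.CalcMolDescriptors(mol)
            rowvals = [vals[n] for n in names]
        except Exception:
            w.writerow([ident, "descriptor_failure"] + [""] * len(names))
            continue
        if any(v is None or (isinstance(v, float) and not math.isfinite(v))
               for v in rowvals):
            w.writerow([ident, "nonfinite_descriptor"] + [""] * len(names))
            continue
        w.writerow([ident, "ok"] + [repr(float(v)) for v in rowvals])


def make_fp_fn(kind, n_bits, radius):
    if kind == "morgan":
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=radius, fpSize=n_bits)
        return n_bits, gen.GetFingerprint
    if kind == "feat_morgan":
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=radius, fpSize=n_bits,
            atomInvariantsGenerator=rdFingerprintGenerator
            .GetMorganFeatureAtomInvGen())
        return n_bits, gen.GetFingerprint
    if kind == "atom_pair":
        gen = rdFingerprintGenerator.GetAtomPairGenerator(fpSize=n_bits)
        return n_bits, gen.GetFingerprint
    if kind == "torsion":
        gen = rdFingerprintGenerator.GetTopologicalTorsionGenerator(
            fpSize=n_bits)
        return n_bits, gen.GetFingerprint
    if kind == "path":
        gen = rdFingerprintGenerator.GetRDKitFPGenerator(fpSize=n_bits)
        return n_bits, gen.GetFingerprint
    if kind == "avalon":
        return n_bits, lambda m: pyAvalonTools.GetAvalonFP(m, nBits=n_bits)
    if kind == "layered":
        return n_bits, lambda m: Chem.LayeredFingerprint(m, fpSize=n_bits)
    if kind == "maccs":
        return 167, MACCSkeys.GenMACCSKeys
    if kind == "pattern":
        return n_bits, lambda m: Chem.PatternFingerprint(m, fpSize=n_bits)
    raise ValueError("unsupported fingerprint kind: " + kind)


def fingerprints(rows, out, args):
    width, fp_fn = make_fp_fn(args["kind"], int(args["n_bits"]),
                              int(args.get("radius", 2)))
    w = csv.writer(out)
    w.writerow(["compound_id", "status"] +
               ["bit_%04d" % (i + 1) for i in range(width)])
    for ident, smiles in rows:
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            w.writerow([ident, "invalid_structure"] + [""] * width)
            continue
        bv = fp_fn(mol)
        bits = ["0"] * width
        for i in bv.GetOnBits():
            bits[i] = "1"
        w.writerow([ident, "ok"] + bits)


PROP_ALIASES = {
    "activity_type": ("activity_type", "standard_type", "type"),
    "activity_value": ("activity_value", "standard_value", "value"),
    "year": ("year", "document_year"),
    "compound_id": ("compound_id", "chembl_id", "molecule_chembl_id", "id"),
}


def get_prop(mol, key):
    props = {k.lower(): v for k, v in mol.GetPropsAsDict().items()}
    for alias in PROP_ALIASES[key]:
        if alias in props:
            return props[alias]
    return ""


def parse_sdf(path, out):
    w = csv.writer(out)
    w.writerow(["compound_id", "smiles", "activity_type", "activity_value",
                "year"])
    supplier = Chem.SDMolSupplier(path, sanitize=True)
    for i, mol in enumerate(supplier):
        if mol is None:
            w.writerow(["MOL_%d" % (i + 1), "", "", "", ""])
            continue
        ident = get_prop(mol, "compound_id") or (
            mol.GetProp("_Name") if mol.HasProp("_Name") and
            mol.GetProp("_Name") else "MOL_%d" % (i + 1))
        w.writerow([ident, Chem.MolToSmiles(mol),
                    get_prop(mol, "activity_type"),
                    get_prop(mol, "activity_value"),
                    get_prop(mol, "year")])


def main(argv):
    cmd = argv[1]
    if cmd == "version":
        with open(argv[2], "w", encoding="utf-8") as out:
            json.dump({"toolkit": "rdkit", "version": rdkit.__version__,
                       "n_descriptors": len(Descriptors.descList)}, out)
        return 0
    infile, outfile = argv[2], argv[3]
    with open(outfile, "w", newline="", encoding="utf-8") as out:
        if cmd == "canonicalize":
            canonicalize(read_tsv(infile), out)
        elif cmd == "descriptors":
            descriptors(read_tsv(infile), out)
        elif cmd == "fingerprints":
            fingerprints(read_tsv(infile), out, json.loads(argv[4]))
        elif cmd == "parse_sdf":
            parse_sdf(infile, out)
        else:
            raise ValueError("unknown command: " + cmd)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
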