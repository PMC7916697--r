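"""Compute Crippen logP, Ertl-Schuffenhauer SA score and Bickerton QED for
SMILES read from a tab-separated file (smiles<TAB>id per line); emits JSON."""
import json
import os
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import Crippen, QED, RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def main(path):
    records = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            parts = line.split("\t")
            smiles = parts[0]
            ident = parts[1] if len(parts) > 1 else smiles
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                print(json.dumps({"error": "unparseable SMILES", "input": smiles}))
                sys.exit(2)
            records.append(
                {
                    "id": ident,
                    "smiles": smiles,
                    "logp": Crippen.MolLogP(mol),
                    "sas": sascorer.calculateScore(mol),
                    "qed": QED.qed(mol),
                }
            )
    print(json.dumps({"rdkit_version": rdBase.rdkitVersion, "records": records}))


if __name__ == "__main__":
    main(sys.argv[1])
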