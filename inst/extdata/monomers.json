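{
  "_comment": "Extender building blocks, one per substrate label. Each block is the two-carbon unit contributed by one extension module, drawn in its unreduced (beta-keto) state: alpha_atom is the alpha-carbon that condenses onto the upstream chain carbonyl; carbonyl_atom is the thioester-derived carbonyl carbon extended by the next unit (or released as the acid). Atom indices are 1-based positions in the SMILES atom order.",
  "mal":   {"smiles": "CC=O",        "alpha_atom": 1, "carbonyl_atom": 2,
            "name": "malonyl-CoA extender"},
  "mmal":  {"smiles": "C(C)C=O",     "alpha_atom": 1, "carbonyl_atom": 3,
            "name": "methylmalonyl-CoA extender (methyl branch)"},
  "emal":  {"smiles": "C(CC)C=O",    "alpha_atom": 1, "carbonyl_atom": 4,
            "name": "ethylmalonyl-CoA extender (ethyl branch)"},
  "mxmal": {"smiles": "C(OC)C=O",    "alpha_atom": 1, "carbonyl_atom": 4,
            "name": "methoxymalonyl-ACP extender (methoxy branch)"},
  "hmal":  {"smiles": "C(O)C=O",     "alpha_atom": 1, "carbonyl_atom": 3,
            "name": "hydroxymalonyl-ACP extender (hydroxyl branch)"}
}
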