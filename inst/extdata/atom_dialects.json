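{
  "comment": "Residue-naming dialects. PDB uses chemical-component codes per anomer; GLYCAM encodes the monosaccharide as one letter (lowercase for L-sugars) plus the anomer (A/B), prefixed by a linkage-position code which is not validated here. Atom names (C1..C6, O2..O6, O5 ring oxygen) are shared by both dialects.",
  "PDB": {
    "GlcNAc": { "a": ["NDG"], "b": ["NAG"] },
    "Man":    { "a": ["MAN"], "b": ["BMA"] },
    "Gal":    { "a": ["GLA"], "b": ["GAL"] },
    "Fuc":    { "a": ["FUC"], "b": ["FUL"] },
    "Xyl":    { "a": ["XYS"], "b": ["XYP"] },
    "Glc":    { "a": ["GLC"], "b": ["BGC"] },
    "Sia":    { "a": ["SIA"], "b": ["SIA"] }
  },
  "GLYCAM": {
    "GlcNAc": "Y",
    "Man": "M",
    "Gal": "L",
    "Fuc": "f",
    "Xyl": "X",
    "Glc": "G",
    "Sia": "S"
  }
}
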