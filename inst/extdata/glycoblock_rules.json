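{
  "format_version": 1,
  "comment": "Data-driven glycoblock vocabulary and sequence-to-propensity rule base. Reference populations are annotation metadata from microsecond-scale MD reported for the corresponding glycoforms; they are carried for context and are never recomputed by this package.",
  "block_vocabulary": {
    "chitobiose_core": {
      "descriptor": "Reducing-end GlcNAc-b(1-4)-GlcNAc unit; rigid, single dominant conformer. Core fucoses attach here: a(1-3)-Fuc stacks against the second GlcNAc and rotates the GlcNAc-b(1-4)-GlcNAc psi by about 20 degrees; a(1-6)-Fuc sits on the opposite face and leaves the linkage unperturbed."
    },
    "trimannose_core": {
      "descriptor": "Central b-Man with the a(1-3)/a(1-6) branching mannoses; the a(1-6) torsions carry the open/folded arm equilibrium. A b(1-2)-Xyl modifier occupies the centre of this unit, rigidifies the (1-3) arm and sterically blocks the front fold; its ring also populates the 1C4 chair (reference: 76% within an N-glycan scaffold)."
    },
    "arm_GlcNAc": {
      "descriptor": "Unbranched b(1-2)-GlcNAc extension of an arm mannose; flexible two-conformer linkage unless restrained by a central xylose."
    },
    "terminal_Gal_1_3": {
      "descriptor": "Plant-type terminal Gal-b(1-3); extends the arm and slightly stabilises the outstretched (1-6)-arm conformation."
    },
    "terminal_Gal_1_4": {
      "descriptor": "Mammalian-type terminal Gal-b(1-4); enables folding of the (1-6) arm over the chitobiose by stacking."
    },
    "LeA_terminus": {
      "descriptor": "Lewis A unit Gal-b(1-3)[Fuc-a(1-4)]GlcNAc; rigid closed conformation; its branching geometry supports hydrogen-bonded arm-arm contacts."
    },
    "LeX_terminus": {
      "descriptor": "Lewis X unit Gal-b(1-4)[Fuc-a(1-3)]GlcNAc; rigid closed conformation; the fucose deoxy-C6 position prevents the arm-arm network that LeA supports."
    }
  },
  "vocabulary_notes": "Terminal galactose and arm GlcNAc are modelled as separate block types; whether the original block inventory merges them cannot be determined from the available material, so the finer-grained split is used and flagged here.",
  "rules": [
    {
      "id": "R1",
      "priority": 40,
      "condition": { "has_fuc13": true },
      "effects": { "bias": "open", "psi_shift": -20 },
      "anchor": "Core a(1-3)-Fuc occupies a single stable stacked position against the chitobiose b(1-4)-GlcNAc, imposing a ~20 degree rotation of the GlcNAc-b(1-4)-GlcNAc psi (reference mean psi -127.8 (14.8) without it) and pushing the (1-6)-arm equilibrium towards the outstretched conformation.",
      "reference_populations": { "ngf_open_pct": 66, "gf_open_pct": 72 }
    },
    {
      "id": "R2",
      "priority": 40,
      "condition": { "has_xyl": true },
      "effects": { "bias": "open", "note": "front fold sterically blocked; (1-3) arm restrained" },
      "anchor": "b(1-2)-Xyl sits in front of the two arms: steric hindrance rigidifies the (1-3) arm, prevents a front fold of the (1-6) arm and pushes its equilibrium open; the xylose ring itself flips between 4C1 and 1C4 chairs.",
      "reference_populations": { "xyl_1C4_chair_pct": 76 }
    },
    {
      "id": "R3",
      "priority": 80,
      "condition": { "arm16_terminal": "terminal_Gal_1_4", "has_fuc16": true },
      "effects": { "prediction": "closed_dominant" },
      "anchor": "Core a(1-6)-Fuc stacks the terminal b(1-4)-Gal of the folded (1-6) arm (with xylose contributing hydrogen bonding when present), making the closed arm the dominant conformer even against open-pushing modifiers.",
      "reference_populations": { "xyl_FA2G2_closed_pct": 70.0, "double_fucose_A2G2_closed_pct": 85 }
    },
    {
      "id": "R4",
      "priority": 45,
      "condition": { "arm16_terminal": "terminal_Gal_1_4", "has_fuc16": false, "has_xyl": false },
      "effects": { "prediction": "mixed", "note": "closed-leaning: b(1-4)-Gal termini favour folding over the chitobiose" },
      "anchor": "A b(1-4)-Gal-terminated (1-6) arm folds over the chitobiose by stacking; without core a(1-6)-Fuc or xylose the fold is favoured but not locked.",
      "reference_populations": { "A2G2_closed_pct": 74 }
    },
    {
      "id": "R4b",
      "priority": 50,
      "condition": { "arm16_terminal": "terminal_Gal_1_4", "has_fuc16": false, "open_bias_modifier": true },
      "effects": { "prediction": "mixed", "note": "competition: open-pushing modifier versus fold-stabilising b(1-4)-Gal stacking" },
      "anchor": "b(1-2)-Xyl hinders but does not prevent folding when the terminal galactose is b(1-4)-linked: the fold survives, slightly distorted (median psi shifted ~20 degrees) and reduced in population.",
      "reference_populations": { "xyl_A2G2_closed_pct": 57 }
    },
    {
      "id": "R5",
      "priority": 100,
      "condition": { "both_lea": true },
      "effects": { "prediction": "restrained_interacting" },
      "anchor": "LeA branching on both arms promotes a stable hydrogen-bonded interaction between the arms (possibly involving the central xylose), restraining the (1-6) arm in conformations otherwise not significantly populated.",
      "reference_populations": {}
    },
    {
      "id": "R6",
      "priority": 90,
      "condition": { "both_lex": true },
      "effects": { "prediction": "open_dominant" },
      "anchor": "With LeX termini the arms do not interact (non-complementary fucose deoxy-C6 position) and the (1-6) arm is predominantly extended; the residual closed form goes through rotation around the core Man-b(1-4)-GlcNAc.",
      "reference_populations": { "lex_open_pct": 90 }
    },
    {
      "id": "R7",
      "priority": 60,
      "condition": { "gal13_terminal_present": true, "open_bias_modifier": true },
      "effects": { "prediction": "open_dominant" },
      "anchor": "Terminal b(1-3)-Gal further stabilises the outstretched (1-6) arm on top of the open push of core a(1-3)-Fuc and/or b(1-2)-Xyl.",
      "reference_populations": { "gfx_open_pct": 87 }
    },
    {
      "id": "R8",
      "priority": 30,
      "condition": { "has_fuc13": true, "has_xyl": true },
      "effects": { "note": "core Man-b(1-4)-GlcNAc linkage more flexible; rotated-trimannose conformer accessible" },
      "anchor": "With both a(1-3)-Fuc and b(1-2)-Xyl the rotation of the trimannose group relative to the chitobiose becomes significantly populated (synergistic hydrogen-bond network); b(1-3)-Gal capping of the arms suppresses it again.",
      "reference_populations": { "ngfx_rotated_core_pct_floor": 20, "gfx_rotated_core_pct": 5 }
    },
    {
      "id": "Rdefault",
      "priority": 0,
      "condition": {},
      "effects": { "prediction": "mixed", "note": "no modifier rules apply; open-leaning two-state arm equilibrium" },
      "anchor": "Unmodified biantennary scaffolds with b(1-2)-GlcNAc (or b(1-3)-Gal) termini keep a mixed open/folded (1-6)-arm equilibrium.",
      "reference_populations": { "man3_open_pct": 85, "A2_open_pct": 52 }
    }
  ]
}
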