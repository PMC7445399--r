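{
  "format_version": 1,
  "comment": "Data-driven shorthand registry for named glycoforms. Sequences are condensed IUPAC-like text; the rightmost residue is the reducing end. Shorthand letters: f = core Fuc-a(1-3) on the reducing-end GlcNAc, x = Xyl-b(1-2) on the central Man, g = both arms capped with Gal-b(1-3), ng = arms left at GlcNAc-b(1-2).",
  "glycoforms": [
    {
      "name": "man3",
      "aliases": ["Man3", "core"],
      "family": "core",
      "sequence": "Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": ""
    },
    {
      "name": "ng",
      "aliases": [],
      "family": "plant",
      "sequence": "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": ""
    },
    {
      "name": "g",
      "aliases": [],
      "family": "plant",
      "sequence": "Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": ""
    },
    {
      "name": "ngf",
      "aliases": [],
      "family": "plant",
      "sequence": "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": ""
    },
    {
      "name": "gf",
      "aliases": [],
      "family": "plant",
      "sequence": "Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": ""
    },
    {
      "name": "ngx",
      "aliases": [],
      "family": "plant",
      "sequence": "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": ""
    },
    {
      "name": "gx",
      "aliases": [],
      "family": "plant",
      "sequence": "Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": ""
    },
    {
      "name": "ngfx",
      "aliases": [],
      "family": "plant",
      "sequence": "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": ""
    },
    {
      "name": "gfx",
      "aliases": [],
      "family": "plant",
      "sequence": "Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": ""
    },
    {
      "name": "lea",
      "aliases": ["LeA", "lea-plant"],
      "family": "plant",
      "sequence": "Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": "Lewis A termini on both arms of the core a(1-3)-fucosylated, b(1-2)-xylosylated biantennary scaffold. AMBIGUITY: the source figures do not print full condensed sequences; both-arm LeA capping is taken from the figure captions describing the LeA-terminated construct."
    },
    {
      "name": "lex",
      "aliases": ["LeX", "lex-hybrid"],
      "family": "hybrid",
      "sequence": "Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc",
      "notes": "Schistosome-type construct: LeX termini on both arms of the same core a(1-3)-Fuc + b(1-2)-Xyl scaffold as 'lea'. AMBIGUITY: arm-terminus detail inferred from the comparison-figure caption, not a printed sequence."
    },
    {
      "name": "a2g2",
      "aliases": ["A2G2"],
      "family": "mammalian",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": "Mammalian biantennary baseline with terminal b(1-4)-Gal."
    },
    {
      "name": "fa2g2",
      "aliases": ["FA2G2"],
      "family": "mammalian",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc",
      "notes": "Mammalian core a(1-6)-fucosylated biantennary baseline."
    },
    {
      "name": "xa2g2",
      "aliases": ["xyl-A2G2", "xA2G2"],
      "family": "hybrid",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)GlcNAc",
      "notes": "b(1-2)-xylosylated A2G2 hybrid."
    },
    {
      "name": "xfa2g2",
      "aliases": ["xyl-FA2G2", "xFA2G2"],
      "family": "hybrid",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc",
      "notes": "b(1-2)-xylosylated, core a(1-6)-fucosylated A2G2 (schistosome-type)."
    },
    {
      "name": "xfa2",
      "aliases": ["xyl-FA2", "xFA2"],
      "family": "hybrid",
      "sequence": "GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc",
      "notes": "b(1-2)-xylosylated, core a(1-6)-fucosylated, non-galactosylated hybrid."
    },
    {
      "name": "xffa2g2",
      "aliases": ["xyl-double-fucose-A2G2"],
      "family": "hybrid",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)][Fuc(a1-3)]GlcNAc",
      "notes": "b(1-2)-xylosylated double-core-fucosylated A2G2 hybrid."
    },
    {
      "name": "ffa2g2",
      "aliases": ["a13F-FA2G2", "double-fucose-A2G2"],
      "family": "hybrid",
      "sequence": "Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)][Fuc(a1-3)]GlcNAc",
      "notes": "Double core fucosylation (a(1-3) + a(1-6)) on a b(1-4)-Gal-terminated A2G2, the worm/fly-cell pattern."
    }
  ]
}
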