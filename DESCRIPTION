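Package: glycanarch
Title: Conformational Architecture of Plant and Hybrid N-Glycans from
    Atomistic Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the three-dimensional architecture of
    plant, invertebrate and hybrid N-glycans from atomistic coordinate
    ensembles. Represents glycans as rooted monosaccharide trees with a
    shorthand registry for the common plant glycoforms, extracts glycosidic
    phi/psi/omega torsion series from multi-model PDB or DCD trajectories,
    summarises them with circular statistics, clusters conformers with a
    density-based method under a toroidal metric with wrapped kernel density
    landscapes and a per-trajectory convergence rule, classifies pyranose
    ring puckers (4C1/1C4 via Cremer-Pople coordinates) and (1-6)-arm states
    (open, front fold, back fold, rotated core), and decomposes glycans into
    "glycoblocks" with a data-driven rule base that predicts qualitative
    conformational propensity from sequence. A seed-deterministic synthetic
    ensemble generator (von Mises torsion mixtures, built ring and
    disaccharide geometries, dwell-structured state-flip series) provides
    ground-truth-known inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
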