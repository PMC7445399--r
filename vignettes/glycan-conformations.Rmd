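---
title: "Methods: conformational analysis of N-glycan ensembles"
author: "glycanarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational analysis of N-glycan ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanarch)
```

## The problem

N-glycans are branched oligosaccharides attached to asparagine residues of
proteins. All share a chitobiose (GlcNAc-β(1-4)-GlcNAc) plus trimannose
(Man3) core from which two "arms" stem; plant and invertebrate glycoforms
decorate this core with motifs absent from mammals — core α(1-3)-fucose,
β(1-2)-xylose on the central mannose, β(1-3)-linked terminal galactose and
Lewis A termini — and these motifs reshape the 3D conformational equilibrium
of the molecule, most visibly the open/folded equilibrium of the (1-6) arm.
Because glycans are intrinsically flexible, their structure is an ensemble
property: the quantities of interest are the per-linkage glycosidic torsion
distributions (φ, ψ and, for 1→6 linkages, ω), the conformer clusters those
distributions occupy with their populations, pyranose ring pucker states,
and discrete arm states (open, front fold, back fold, rotated core).

`glycanarch` implements that analysis chain for atomistic coordinate
ensembles, plus a sequence-level layer: a decomposition of any glycoform
into "glycoblocks" — self-contained spatial units (chitobiose core with its
fucoses, trimannose core with its xylose, arm units and termini) — and a
data-driven rule base that predicts the qualitative direction of the
(1-6)-arm equilibrium from the blocks alone.

## Torsion conventions

For a linkage X(1→n)Y the package measures

* φ = O5(X)–C1(X)–On(Y)–Cn(Y)
* ψ = C1(X)–On(Y)–Cn(Y)–C(n−1)(Y)
* ω = O6(Y)–C6(Y)–C5(Y)–O5(Y), for n = 6 only,

with the IUPAC sign convention (clockwise positive sighting along the
central bond) and everything reported in degrees in (−180, 180]. For
2-linked substituents (β(1-2)-Xyl, the arm GlcNAcs) the fourth ψ atom is C1
of the parent, the natural n−1 continuation. The ω rotamers gg/gt/tg sit at
−60°, +60° and 180°. These are the standard carbohydrate-NMR conventions and
are consistent with the gg/gt/tg naming; they are configurable only through
the torsion-definition table, not scattered through the code.

Circular statistics use the mean-resultant convention: the mean direction is
`atan2(mean sin, mean cos)` and the circular SD is \(\sqrt{-2\ln R}\) in
degrees (Mardia). Whether published "mean (SD)" torsion tables use circular
or linear SDs is rarely stated; the circular SD is the convention of the
trajectory-analysis tools of this field and is what the convergence rule
below consumes. For a von Mises sample the closed form
\(\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}\) provides an independent check,
used in the test suite.

## Conformer clustering on the torus

Populations per linkage are computed by density-based clustering
(DBSCAN-family) of the φ/ψ pair (and of ω separately, one-dimensionally)
under the toroidal metric: per-dimension shortest angular difference,
combined Euclidean-wise. Parameters, all surfaced to the user:

* `eps = 25°` — neighbourhood radius. Torsion basins of glycosidic linkages
  are tens of degrees wide and separated by ≳90°, so the result is flat over
  a broad range of `eps`.
* `minPts = max(5, 0.002 n)` — core-point weight; scales with sample size so
  the density floor is a fixed fraction of the data.
* `minFraction = 0.01` — clusters below 1% of frames are merged into noise
  rather than reported as conformers.
* `binWidth = 2°` — implementation detail: the sample is quantised onto a
  fine periodic histogram and the density rule runs on weighted cells, which
  makes the procedure O(n + m²) in the number m of occupied cells instead of
  O(n²). The quantisation is an order of magnitude below `eps`; populations
  and per-cluster circular means/SDs are always computed from the original
  values, not the bins.

Noise frames are reported as their own row, never dropped; count-based
populations plus noise sum to one exactly. Labels are assigned by descending
population (1 = most populated). Because the metric wraps, a mode straddling
±180° is a single cluster — the test suite checks this explicitly.

Heat-map landscapes use a binned kernel density estimate with a wrapped
Gaussian kernel (default bandwidth 10°, 90×90 grid, i.e. 4° cells),
normalised to integrate to one over the torus. The bandwidth is a display
parameter, not an inference parameter: clustering never consumes the KDE.

### Convergence rule

Sampling sufficiency is assessed per trajectory: a trajectory is flagged
`extend` when any cluster of any of its landscapes has a per-dimension
circular SD strictly above 15°, otherwise `converged`. The comparison is a
strict inequality (an SD of exactly 15.0° converges); "significantly larger
than 15°" is read as strict exceedance, and the boundary decision is frozen
here so it cannot drift between analyses. When several trajectory files are
given (e.g. separate runs started from each ω rotamer), the pipeline reports
both pooled populations (equal frame weighting — the weighting across
rotamer-started runs is recorded in the manifest) and per-trajectory
convergence.

## Ring pucker

The canonical classifier uses Cremer–Pople puckering coordinates of the six
ring atoms ordered O5, C1..C5: total amplitude Q (Å), polar angle θ and
azimuth φ. θ ≤ 45° is the ⁴C₁ chair, θ ≥ 135° the ¹C₄ chair, anything else
(boat/twist-boat band, or Q < 0.1 Å) is `other`. The two-torsion projection
t1 = C1–C2–C3–C4, t2 = C2–C3–C4–C5 used in ring-flip scatter plots is
always reported alongside, and a sign-quadrant heuristic on (t1, t2) is kept
as a documented cross-check (≥99% agreement on synthetic flip ensembles);
classification itself needs the total, rotation-invariant CP rule. Because
CP coordinates depend on where the traversal starts, the classifier rolls
the ring so O5 is atom 1; callers presenting a differently-ordered ring pass
`origin`. Mirror inversion maps ⁴C₁ ↔ ¹C₄, which the builders and tests use
as a symmetry check.

## Arm-state classification

Frames are labelled `open`, `front_fold`, `back_fold` or `rotated_core`:

* `rotated_core` first, with precedence: the core Man-β(1-4)-GlcNAc ψ more
  than `psiTol = 90°` from its reference mode (default: the KDE mode of the
  observed series) marks rotation of the whole trimannose group relative to
  the chitobiose, a distinct conformer regardless of arm distance.
* otherwise `open` when the distance from the arm-terminus ring centroid to
  the chitobiose centroid (mean of the two GlcNAc ring centroids) exceeds
  `dOpen = 8 Å`. No boundary is printed in the literature for this state;
  8 Å separates the constructed folded (≈5 Å) and outstretched (≳12 Å)
  geometries with a wide margin, is configurable, and is logged in every
  manifest. Labels are provably insensitive to ±0.5 Å shifts of `dOpen`
  except for frames inside that distance band.
* otherwise front/back by the side of the root-GlcNAc ring mean plane the
  arm centroid occupies. "Front" is defined by the right-hand rule over the
  O5→C1→C2 traversal of the root ring — a deterministic restatement of the
  pictorial "towards the reader" convention.

An alternative, torsion-space route to the same taxonomy — classifying the
α(1-6) φ/ψ/ω clusters through `statePopulations()` with a user predicate —
is provided because published open/closed assignments may be cluster-based
rather than distance-based; which one a given study used is usually
unstated. Both are exposed; the geometric one is the default in the
pipeline.

## Glycoblocks and the rule base

`decomposeGlycoblocks()` partitions a glycan by precedence: chitobiose core
(absorbing core fucoses as modifiers), trimannose core (absorbing the
β(1-2)-Xyl), Lewis A/X termini (absorbing their GlcNAc), then remaining arm
GlcNAcs and unbranched terminal galactoses. Terminal galactose and arm
GlcNAc are kept as separate block types — the coarser alternative (one
merged "arm extension" type) cannot be ruled in or out from the available
material, and the finer split loses nothing; this is flagged in the
vocabulary file. The propensity rules live in a versioned JSON file
(`inst/extdata/glycoblock_rules.json`), each with an explicit integer
priority, a paraphrased evidence anchor and annotated reference populations
from microsecond-scale MD. Those percentages are metadata carried for
context: reproducing them requires μs sampling and is deliberately out of
scope, so the engine predicts directions, never numbers. Rules with an
explicit prediction (Lewis termini, the fucose/galactose closed lock)
override the open-bias aggregation of the modifier rules; ties and conflicts
resolve by priority and are logged in the trace. One rule (R4b) damps the
open push of β(1-2)-Xyl to `mixed` when the (1-6) arm ends in β(1-4)-Gal
without core α(1-6)-Fuc, reflecting that the galactose-stacking fold
survives xylosylation with reduced population.

## The synthetic generator

The generators stand in for μs-scale MD and define the package's study
conditions; every generator returns its ground truth with the data, and all
recovery tests consume only the data.

* **Torsion mixtures**: independent von Mises components per dimension
  (Best–Fisher sampling on the R RNG, so byte-reproducible under a seed).
  κ = 50 (circular SD ≈ 8°) is the default test concentration — a typical
  within-basin spread for glycosidic torsions — with components placed ≥90°
  apart, as real rotamer basins are.
* **Flip series**: a k-state Markov chain with geometric dwells; mean dwells
  6 and 2 frames give the 3:1 ratio (stationary 0.75/0.25) used in the
  ring-flip recovery tests.
* **Rings**: six-membered rings synthesised at exact Cremer–Pople
  coordinates (default Q = 0.57 Å, a typical pyranose amplitude). The ring
  radius is set from the mean of the standard 1.52 Å C–C / 1.43 Å C–O bond
  lengths, so CP coordinates — the classified quantity — are exact while
  individual bond lengths are approximate.
* **Linked fragments**: internal-coordinate (NeRF) chain construction;
  glycosidic φ/ψ/ω are placed directly, so measured dihedrals equal the
  request to numerical precision, and each ring is completed as a rigid
  ideal chair. No force-field relaxation: geometry only needs to realise the
  requested internal coordinates. Frames with atoms closer than 0.5 Å are
  kept but flagged.
* **Arm scaffolds**: labelled Man3 geometries with the arm centroid placed
  at a requested distance and plane side. The residues are rigid rings, not
  covalently joined — these are classifier test fixtures, not molecules.

What passing on these inputs shows — and what it does not: recovery of
known mixtures, flips and placements demonstrates that the measurement,
clustering and classification machinery is correct and deterministic. It
does not show that a given force field samples the right basins, nor that
real populations match the annotated reference percentages; those are
properties of the MD, not of this analysis layer.

## Problem sizes and numerical choices

The shipped tests use n = 10⁴–10⁵ frames for statistical checks, 3×10⁴
frames per mixture across 20 seeds for weight recovery (tolerance: three
binomial standard errors), 100 rigid-transformed rings per pucker state, and
2000-frame disaccharide ensembles for the end-to-end pipeline — sizes chosen
so the whole suite runs in minutes on one CPU while leaving the statistical
tolerances comfortably non-trivial. Angles are degrees everywhere in the
API; radians exist only inside trigonometric kernels. Dihedrals raise an
error on collinear geometry rather than returning a conventional value.
PDB coordinates round-trip at the format's 10⁻³ Å precision; analysis
outputs are written with fixed decimal formatting so identical
configurations yield byte-identical tables.

## Limitations

* Torsion-space only: no RMSD-based structural clustering, no free-energy
  conversion, no Markov-state modelling, no hydrogen-bond network
  enumeration — the stabilising interactions discussed alongside the rule
  anchors are narrative context, not computed quantities.
* Sialylated glycans parse (as `Sia`/`Neu5Ac` tokens) but are rejected by
  the torsion layer; the α(2→3/6) chemistry is a placeholder.
* Trajectory formats: multi-model PDB and DCD. XTC/NetCDF readers are not
  available in this build and are rejected with a clear error.
* The atom-name dialects validate residue naming (PDB chemical-component
  codes; GLYCAM position-letter-anomer codes) and assume ensemble residues
  appear in tree order, which holds for all files this package writes.
* Reference populations in the rule base are annotations; the package never
  claims to recompute them.
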