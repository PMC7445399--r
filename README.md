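# glycanarch

Conformational architecture of plant, invertebrate and hybrid N-glycans
from atomistic coordinate ensembles.

N-glycans — the branched oligosaccharides attached to asparagine residues
of proteins — are flexible molecules whose biology is driven by ensemble
properties: which conformers the glycosidic linkages occupy, how populated
each is, whether a pyranose ring flips its chair, and whether the (1-6) arm
is outstretched ("open") or folded over the chitobiose core. Plant and
invertebrate motifs (core α(1-3)-fucose, β(1-2)-xylose, β(1-3)-galactose,
Lewis A termini) shift these equilibria and are immunogenic in humans, which
makes their structural consequences worth quantifying. `glycanarch` is an R
package for exactly that analysis layer, for people who run carbohydrate MD
or work with multi-model glycan structures.

## What it computes

For a linkage X(1→n)Y the glycosidic torsions are

* φ = O5(X)–C1(X)–On(Y)–Cn(Y)
* ψ = C1(X)–On(Y)–Cn(Y)–C(n−1)(Y)
* ω = O6(Y)–C6(Y)–C5(Y)–O5(Y) for 1→6 linkages (rotamers gg/gt/tg at
  −60°/+60°/180°),

summarised with circular statistics (mean direction, circular SD
√(−2 ln R)). Per-linkage conformers come from density-based (DBSCAN-family)
clustering under the toroidal metric, with count-based populations, a noise
row, wrapped-Gaussian KDE landscapes, and a per-trajectory convergence rule
(flag `extend` iff any cluster's circular SD strictly exceeds 15°). Ring
puckers are classified through Cremer–Pople coordinates (θ ≤ 45° → ⁴C₁,
θ ≥ 135° → ¹C₄), arm states geometrically (open / front fold / back fold /
rotated core). A sequence-level layer decomposes any glycoform into
"glycoblocks" (chitobiose core + fucoses, trimannose core + xylose, arm
units, termini) and predicts the qualitative direction of the (1-6)-arm
equilibrium from a versioned JSON rule base. A seed-deterministic synthetic
generator (von Mises torsion mixtures, exact-pucker rings, NeRF-built
fragments, labelled arm scaffolds) provides ground-truth-known inputs in
place of μs-scale MD.

## Worked example

Parse the doubly-modified, galactosylated plant glycoform *gfx*, decompose
it into glycoblocks and predict its arm propensity:

```r
library(glycanarch)
tree <- parseGlycan("gfx")
tree
#> GlycanTree: 11 residues, 10 linkages
#>   Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-3)GlcNAc(b1-2)Man(a1-6)][Xyl(b1-2)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc

decomposeGlycoblocks(tree)
#> GlycoblockSet: 6 blocks over 11 residues
#>   [core] chitobiose_core  residues: 1,2,3  modifiers: Fuc_a1_3
#>   [core] trimannose_core  residues: 4,5,6,9  modifiers: Xyl_b1_2
#>   [1-3] arm_GlcNAc  residues: 10
#>   [1-3] terminal_Gal_1_3  residues: 11
#>   [1-6] arm_GlcNAc  residues: 7
#>   [1-6] terminal_Gal_1_3  residues: 8

predictPropensity(tree)
#> PropensityReport
#>   (1-6) arm: open_dominant
#>   chitobiose psi shift: -20 deg
#>   rules fired: R7, R1, R2, R8
```

The fired rules say: core α(1-3)-Fuc rotates the chitobiose ψ by ≈ −20° and
pushes the arm open (R1), β(1-2)-Xyl blocks the front fold (R2), β(1-3)-Gal
termini stabilise the open arm further (R7), and the Fuc+Xyl combination
makes the rotated-trimannose conformer accessible (R8). Each rule carries
its evidence note and annotated reference populations in the trace.

Ensemble analysis on a synthetic disaccharide with known truth (70/30
two-conformer mixture):

```r
sim <- runSimulate(list(
  glycan = "Man(b1-4)GlcNAc",
  components = list(list(mean = c(60, 180),  kappa = 50, weight = 0.7),
                    list(mean = c(-60, -120), kappa = 50, weight = 0.3)),
  n_frames = 2000, seed = 42), "sim-out")

res <- runAnalyze(list(topology = sim$paths$pdb,
                       glycan = "Man(b1-4)GlcNAc"), "analysis-out")
read.csv(res$paths$populations)
#>             linkage torsion cluster mean_deg sd_deg population_pct
#> 1 Man2(b1-4)GlcNAc1     phi       1    59.94   8.24           69.8
#> 2 Man2(b1-4)GlcNAc1     phi       2   -60.09   7.49           30.2
#> 3 Man2(b1-4)GlcNAc1     psi       1  -179.49   8.21           69.8
#> 4 Man2(b1-4)GlcNAc1     psi       2  -120.71   8.11           30.2

convergenceFlags(res$convergence)
#>      pooled
#> "converged"
```

The two clusters sit at the generated modes (φ ≈ 60/−60, ψ ≈ 180/−120, each
with the ≈8° circular SD implied by κ = 50) and the populations recover the
mixture weights; every cluster SD is below 15°, so the convergence rule
reports `converged`. `analysis-out/` also contains the long-format torsion
series, the wrapped-KDE grid with its metadata, and a manifest (inputs
hashed, parameters, package version) sufficient to reproduce the run
byte-for-byte.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/glycanarch-cli.R blocks --glycan gfx --out blocks-out
```

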