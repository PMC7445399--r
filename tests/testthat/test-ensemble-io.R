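test_that("multi-model PDB write/read round-trips to format precision", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  tor <- matrix(c(rep(60, 5), seq(-150, -30, by = 30)), 5, 2,
                dimnames = list(NULL, defs$label))
  ens <- suppressWarnings(buildLinkedEnsemble(tree, tor))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, path)
  back <- readEnsemble(path)
  expect_equal(nFrames(back), 5)
  expect_equal(nrow(atomTable(back)), nrow(atomTable(ens)))
  expect_lt(max(abs(ensembleCoords(back) - ensembleCoords(ens))), 1e-3)
})

test_that("frames split across files concatenate to the same ensemble", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  tor <- matrix(c(rep(60, 6), seq(-150, 100, length.out = 6)), 6, 2,
                dimnames = list(NULL, defs$label))
  ens <- suppressWarnings(buildLinkedEnsemble(tree, tor))
  whole <- withr::local_tempfile(fileext = ".pdb")
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, whole)
  co <- ensembleCoords(ens)
  writeEnsemblePDB(new("GlycanEnsemble", atoms = atomTable(ens),
                       coords = co[, , 1:2, drop = FALSE]), p1)
  writeEnsemblePDB(new("GlycanEnsemble", atoms = atomTable(ens),
                       coords = co[, , 3:6, drop = FALSE]), p2)
  pooled <- readEnsemble(p1, c(p1, p2))
  onefile <- readEnsemble(whole)
  expect_equal(nFrames(pooled), 6)
  expect_equal(ensembleCoords(pooled), ensembleCoords(onefile))
})

test_that("stride and discard subset frames; empty results are an error", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  tor <- matrix(c(rep(60, 6), seq(-150, 100, length.out = 6)), 6, 2,
                dimnames = list(NULL, defs$label))
  ens <- suppressWarnings(buildLinkedEnsemble(tree, tor))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(ens, path)
  expect_equal(nFrames(readEnsemble(path, stride = 2)), 3)
  expect_equal(nFrames(readEnsemble(path, discard = 4)), 2)
  expect_error(readEnsemble(path, discard = 10), "zero frames")
  expect_error(readEnsemble(tempfile()), "not found")
  expect_error(readEnsemble(path, "frames.xtc"), "not found|not supported")
})

test_that("atom maps validate dialect resnames and completeness", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  ens <- buildLinkedEnsemble(tree)
  map <- mapAtoms(tree, ens, "PDB")
  expect_s4_class(map, "AtomMap")
  # renaming one ring atom breaks resolution with a named error
  a <- atomTable(ens)
  a$name[a$name == "O5" & a$resid == 2][1] <- "OX"
  broken <- new("GlycanEnsemble", atoms = a, coords = ensembleCoords(ens))
  expect_error(mapAtoms(tree, broken, "PDB"), "O5.*residue 2|unresolved")
  # wrong residue label is caught under the PDB dialect
  b <- atomTable(ens)
  b$resname[b$resid == 1] <- "GAL"
  mislabeled <- new("GlycanEnsemble", atoms = b, coords = ensembleCoords(ens))
  expect_error(mapAtoms(tree, mislabeled, "PDB"), "GlcNAc")
  expect_s4_class(mapAtoms(tree, mislabeled, "custom"), "AtomMap")
})

test_that("GLYCAM and PDB labels give identical torsions downstream", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  tor <- matrix(c(55, -100), 1, 2, dimnames = list(NULL, defs$label))
  ensP <- buildLinkedEnsemble(tree, tor, dialect = "PDB")
  ensG <- buildLinkedEnsemble(tree, tor, dialect = "GLYCAM")
  expect_identical(atomTable(ensG)$resname[1], "0YB")
  vP <- torsionValues(torsionSeries(ensP, mapAtoms(tree, ensP, "PDB"), defs))
  vG <- torsionValues(torsionSeries(ensG, mapAtoms(tree, ensG, "GLYCAM"), defs))
  expect_equal(vP, vG)
})

test_that("population tables sum to 100 percent per torsion", {
  spec <- list(dimensions = c("phi", "psi"),
               components = list(
                 list(mean = c(60, 180), kappa = 50, weight = 0.7),
                 list(mean = c(-60, -120), kappa = 50, weight = 0.3)),
               n_frames = 5000, seed = 2)
  mx <- sampleTorsionMixture(spec)
  ls <- clusterTorsions(mx$values, dimensions = c("L1:phi", "L1:psi"))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- writePopulationTable(list(ls), path)
  expect_true(file.exists(path))
  got <- utils::read.csv(path)
  for (tor in unique(got$torsion))
    expect_equal(sum(got$population_pct[got$torsion == tor]), 100,
                 tolerance = 0.1)
  # weights land near the generator truth
  phi1 <- got[got$torsion == "phi" & got$cluster == "1", ]
  expect_lt(abs(phi1$population_pct - 70), 2)

  # single cluster: one row at 100%
  one <- clusterTorsions(rvonmises(2000, 10, 80), dimensions = "L2:phi")
  t1 <- writePopulationTable(list(one), path)
  expect_equal(nrow(t1), 1 + (noiseFraction(one) > 0))
  # empty landscape list: header-only file
  t0 <- writePopulationTable(list(), path)
  expect_equal(nrow(t0), 0)
  expect_equal(nrow(utils::read.csv(path)), 0)
})
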