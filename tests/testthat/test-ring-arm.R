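test_that("built chairs classify to their requested pucker", {
  r4 <- buildPyranose("4C1")
  expect_identical(as.character(puckerStates(classifyPucker(r4$xyz))), "4C1")
  r1 <- buildPyranose("1C4")
  expect_identical(as.character(puckerStates(classifyPucker(r1$xyz))), "1C4")
  boat <- buildPyranose(list(Q = 0.57, theta = 90, phi = 30))
  expect_identical(as.character(puckerStates(classifyPucker(boat$xyz))), "other")

  # Cremer-Pople round trip is exact for generic coordinates
  req <- c(Q = 0.42, theta = 125, phi = 77)
  got <- cremerPople(buildPyranose(as.list(req))$xyz)
  expect_equal(unname(got), unname(req), tolerance = 1e-9)

  expect_error(buildPyranose("4C1", Q = 1.5), "amplitude")
  expect_error(buildPyranose("3S1"), "unknown pucker")
})

test_that("pucker classification survives rigid motion and relabelled origins", {
  set.seed(55)
  for (st in c("4C1", "1C4")) {
    ring <- buildPyranose(st)$xyz
    for (i in 1:20) {
      moved <- randomRigid(ring)
      expect_identical(as.character(puckerStates(classifyPucker(moved))), st)
    }
    # present the ring starting from C3 (origin marks where O5 now sits)
    rolled <- ring[c(4:6, 1:3), ]
    expect_identical(
      as.character(puckerStates(classifyPucker(rolled, origin = 4))), st)
  }
})

test_that("mirror inversion swaps the two chairs and flattens to other", {
  m <- mirrorZ(buildPyranose("4C1")$xyz)
  expect_identical(as.character(puckerStates(classifyPucker(m))), "1C4")
  m2 <- mirrorZ(buildPyranose("1C4")$xyz)
  expect_identical(as.character(puckerStates(classifyPucker(m2))), "4C1")

  hexagon <- buildPyranose(list(Q = 1e-9, theta = 0, phi = 0))$xyz
  hexagon[, 3] <- 0
  expect_identical(as.character(puckerStates(classifyPucker(hexagon))), "other")
})

test_that("the t1/t2 quadrant heuristic agrees with Cremer-Pople on flips", {
  set.seed(66)
  flips <- sampleDwellSeries(c("1C4", "4C1"), c(6, 2), 500, seed = 3)
  rings <- buildPuckerEnsemble(flips$states)
  for (f in seq_len(dim(rings)[3])) rings[, , f] <- randomRigid(rings[, , f])
  ps <- classifyPucker(rings)
  heur <- puckerQuadrant(ps@t1, ps@t2)
  expect_gte(mean(as.character(heur) == as.character(puckerStates(ps))), 0.99)
  expect_identical(as.character(puckerStates(ps)), as.character(flips$states))
})

test_that("pucker populations recover dwell-structured flip fractions", {
  flips <- sampleDwellSeries(c("1C4", "4C1"), c(9, 3), 1e4, seed = 8)
  rings <- buildPuckerEnsemble(flips$states)
  pops <- puckerPopulations(classifyPucker(rings))
  expect_equal(sum(pops), 1, tolerance = 1e-12)
  expect_lt(abs(pops[["1C4"]] - 0.75), 0.02)
  expect_lt(abs(pops[["4C1"]] - 0.25), 0.02)
})

test_that("constructed arm geometries recover their labels", {
  cases <- list(list("open", 14), list("front_fold", 5), list("back_fold", 5))
  for (cs in cases) {
    g <- buildArmGeometry(cs[[1]], cs[[2]], nFrames = 4)
    map <- mapAtoms(g$tree, g$ensemble, "PDB")
    as_ <- classifyArmState(g$ensemble, map, g$tree)
    expect_identical(unique(as.character(armStates(as_))), cs[[1]])
    expect_equal(sum(armStatePopulations(as_)), 1)
  }
  expect_error(buildArmGeometry("open", 1), "distance")
})

test_that("the open boundary only affects frames inside the distance band", {
  # states at distances well outside dOpen +/- 0.5 A are insensitive to
  # shifting the boundary by 0.5 A
  for (dst in c(5, 9.5, 14)) {
    g <- buildArmGeometry("front_fold", dst)
    map <- mapAtoms(g$tree, g$ensemble, "PDB")
    lab1 <- as.character(armStates(classifyArmState(g$ensemble, map, g$tree,
                                                    dOpen = 8)))
    lab2 <- as.character(armStates(classifyArmState(g$ensemble, map, g$tree,
                                                    dOpen = 8.5)))
    expect_identical(lab1, lab2)
  }
})

test_that("a rotated core psi overrides the distance-based labels", {
  g <- buildArmGeometry("open", 14, nFrames = 6)
  map <- mapAtoms(g$tree, g$ensemble, "PDB")
  base <- classifyArmState(g$ensemble, map, g$tree)
  # force a reference mode opposite to the observed constant psi
  flipped <- classifyArmState(g$ensemble, map, g$tree,
                              psiRef = base@psi_core[1] + 150)
  expect_identical(unique(as.character(armStates(flipped))), "rotated_core")
})

test_that("trees without a 1-6 arm are rejected", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  ens <- buildLinkedEnsemble(tree)
  map <- mapAtoms(tree, ens, "PDB")
  expect_error(classifyArmState(ens, map, tree), "")
})
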