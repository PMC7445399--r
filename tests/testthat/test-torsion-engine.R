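test_that("dihedralAngle matches the projection oracle and handles plane cases", {
  expect_equal(dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)), 0)
  expect_equal(dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1)), 180)

  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    p <- randomQuadruple()
    got <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- oracleDihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    worst <- max(worst, abs(angDiff <- ((got - ref + 180) %% 360) - 180))
  }
  expect_lt(worst, 1e-9)

  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("dihedralAngle is invariant under rigid transforms", {
  set.seed(102)
  worst <- 0
  for (i in 1:200) {
    p <- randomQuadruple()
    ref <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    q <- randomRigid(p)
    got <- dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ])
    worst <- max(worst, abs(((got - ref + 180) %% 360) - 180))
  }
  expect_lt(worst, 1e-9)
})

test_that("mirror reflection negates dihedrals", {
  set.seed(103)
  for (i in 1:50) {
    p <- randomQuadruple()
    ref <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
    m <- mirrorZ(p)
    got <- dihedralAngle(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal(abs(((got + ref + 180) %% 360) - 180), 0, tolerance = 1e-9)
  }
})

test_that("circular summaries follow the resultant-length convention", {
  s <- circularSummary(rep(170, 10))
  expect_equal(s$mean, 170)
  expect_equal(s$sd, 0, tolerance = 1e-5)
  expect_equal(s$R, 1)

  # wrap symmetry: angles straddling the discontinuity average to 180
  expect_equal(circularSummary(c(179, -179))$mean, 180)
  expect_equal(circularMean(c(10, 350)), 0)

  # adding multiples of 360 changes nothing
  x <- c(-170, 150, 100, -120)
  expect_equal(circularSummary(x + 720)$mean, circularSummary(x)$mean)
  expect_equal(circularSummary(x - 360)$sd, circularSummary(x)$sd)
})

test_that("von Mises samples reproduce the closed-form circular SD", {
  set.seed(7)
  x <- rvonmises(1e5, -120, 50)
  s <- circularSummary(x)
  expect_lt(abs(((s$mean + 120 + 180) %% 360) - 180), 0.5)
  expect_lt(abs(s$sd - vonMisesSD(50)) / vonMisesSD(50), 0.05)
  expect_true(all(x > -180 & x <= 180))
})

test_that("torsion series recover builder-prescribed angles exactly", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  tor <- matrix(rep(c(60, -120), each = 10), 10, 2,
                dimnames = list(NULL, defs$label))
  ens <- buildLinkedEnsemble(tree, tor)
  map <- mapAtoms(tree, ens, "PDB")
  vals <- torsionValues(torsionSeries(ens, map, defs))
  expect_equal(unname(vals[, defs$label[defs$torsion == "phi"]]),
               rep(60, 10), tolerance = 1e-6)
  expect_equal(unname(vals[, defs$label[defs$torsion == "psi"]]),
               rep(-120, 10), tolerance = 1e-6)

  # a psi ramp sweeping the circle round-trips exactly
  ramp <- seq(-170, 180, by = 10)
  tor2 <- matrix(c(rep(-75, length(ramp)), ramp), ncol = 2,
                 dimnames = list(NULL, defs$label))
  ens2 <- suppressWarnings(buildLinkedEnsemble(tree, tor2))
  vals2 <- torsionValues(torsionSeries(ens2, mapAtoms(tree, ens2, "PDB"), defs))
  expect_equal(unname(vals2[, defs$label[defs$torsion == "psi"]]), ramp,
               tolerance = 1e-6)
})

test_that("omega is only defined on 1-6 linkages", {
  defs14 <- torsionDefinitions(parseGlycan("Man(b1-4)GlcNAc"))
  expect_false("omega" %in% defs14$torsion)
  defs16 <- torsionDefinitions(parseGlycan("Man(a1-6)Man"))
  expect_true("omega" %in% defs16$torsion)
})

test_that("degenerate frames are reported with their index", {
  tree <- parseGlycan("Man(b1-4)GlcNAc")
  defs <- torsionDefinitions(tree)
  ens <- buildLinkedEnsemble(tree, matrix(c(60, -120), 1, 2,
                                          dimnames = list(NULL, defs$label)))
  co <- ensembleCoords(ens)
  # make the psi quadruple collinear in frame 1
  map <- mapAtoms(tree, ens, "PDB")
  d <- defs[defs$torsion == "psi", ]
  i1 <- resolveAtom(map, d$res1, d$atom1)
  i2 <- resolveAtom(map, d$res2, d$atom2)
  i3 <- resolveAtom(map, d$res3, d$atom3)
  co[i1, , 1] <- co[i3, , 1] + 2 * (co[i2, , 1] - co[i3, , 1])
  broken <- new("GlycanEnsemble", atoms = atomTable(ens), coords = co)
  expect_error(torsionSeries(broken, map, defs), "frame")
})

test_that("omega rotamers map to the staggered wells", {
  expect_equal(as.character(omegaRotamer(c(-65, 55, 175, -175))),
               c("gg", "gt", "tg", "tg"))
})
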