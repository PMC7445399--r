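test_that("single residues and registry shorthands parse to valid trees", {
  t1 <- parseGlycan("GlcNAc")
  expect_s4_class(t1, "GlycanTree")
  expect_equal(nrow(glycanNodes(t1)), 1)
  expect_equal(nrow(glycanLinkages(t1)), 0)

  # every registry shorthand expands to a valid tree
  for (nm in registryNames()) {
    tr <- parseGlycan(nm)
    expect_true(validObject(tr), info = nm)
  }
})

test_that("shorthand expansion matches hand-enumerated glycoform topologies", {
  # counts enumerated by hand from the biantennary scaffold: chitobiose (2)
  # + Man3 (3) + per-arm extensions + core modifiers
  sizes <- c(man3 = 5, ng = 7, g = 9, ngf = 8, gf = 10, ngx = 8, gx = 10,
             ngfx = 9, gfx = 11, lea = 13, lex = 13, a2g2 = 9, fa2g2 = 10,
             xa2g2 = 10, xfa2g2 = 11, xfa2 = 9, ffa2g2 = 11, xffa2g2 = 12)
  for (nm in names(sizes)) {
    tr <- parseGlycan(nm)
    expect_equal(nrow(glycanNodes(tr)), unname(sizes[nm]), info = nm)
    expect_equal(nrow(glycanLinkages(tr)), unname(sizes[nm]) - 1, info = nm)
  }
  # ngfx detail: chitobiose + 3 Man + 2 arm GlcNAc + core Fuc + Xyl
  ngfx <- parseGlycan("ngfx")
  counts <- table(glycanNodes(ngfx)$name)
  expect_equal(as.vector(counts[c("GlcNAc", "Man", "Fuc", "Xyl")]),
               c(4, 3, 1, 1))
})

test_that("serialization is canonical and round-trips", {
  for (nm in registryNames()) {
    tr <- parseGlycan(nm)
    s <- serializeGlycan(tr)
    expect_identical(serializeGlycan(parseGlycan(s)), s, info = nm)
    expect_true(isIsomorphic(parseGlycan(s), tr), info = nm)
  }
  expect_identical(serializeGlycan(parseGlycan("GlcNAc")), "GlcNAc")

  # branch entry order does not matter
  a <- parseGlycan("Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc")
  b <- parseGlycan("Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-3)]GlcNAc")
  expect_identical(serializeGlycan(a), serializeGlycan(b))
  expect_true(isIsomorphic(a, b))
})

test_that("parse errors name the offending token and offset", {
  expect_error(parseGlycan("Bogus(b1-4)GlcNAc"), "character 1.*Bogus.*unknown residue")
  expect_error(parseGlycan("Man(a1-3)[Man(a1-6)Man(b1-4)GlcNAc"), "unbalanced")
  expect_error(
    parseGlycan("Man(a1-3)[Fuc(a1-3)][Xyl(b1-3)]Man(b1-4)GlcNAc"),
    "duplicate substitution")
  expect_error(parseGlycan(""), "empty")
  expect_error(parseGlycan("Man(c1-4)GlcNAc"), "linkage")
})

test_that("sialic acid parses but is flagged unsupported for analysis", {
  tr <- parseGlycan("Neu5Ac(a2-6)Gal(b1-4)GlcNAc")
  expect_false(all(glycanNodes(tr)$supported))
  expect_error(torsionDefinitions(tr), "unsupported")
})

test_that("torsion definitions follow the phi/psi/omega conventions", {
  man3 <- parseGlycan("man3")
  defs <- torsionDefinitions(man3)
  expect_equal(nrow(defs), 9)  # 4 linkages x 2 + 1 omega
  expect_equal(sum(defs$torsion == "omega"), 1)

  expect_equal(nrow(torsionDefinitions(parseGlycan("GlcNAc"))), 0)
  expect_equal(nrow(torsionDefinitions(parseGlycan("ngfx"))), 17)

  # atom conventions: phi = O5-C1-On-Cn, psi = C1-On-Cn-C(n-1)
  d <- defs[defs$torsion == "phi", ][1, ]
  expect_identical(c(d$atom1, d$atom2), c("O5", "C1"))
  # the 2-linked xylose psi ends on C1 of the parent
  gx <- parseGlycan("gx")
  dx <- torsionDefinitions(gx)
  xyl_id <- glycanNodes(gx)$id[glycanNodes(gx)$name == "Xyl"]
  psi_x <- dx[dx$child_id == xyl_id & dx$torsion == "psi", ]
  expect_identical(psi_x$atom4, "C1")
  # omega of a 1-6 linkage is O6-C6-C5-O5 on the parent
  om <- dx[dx$torsion == "omega", ]
  expect_identical(unlist(om[, c("atom1", "atom2", "atom3", "atom4")],
                          use.names = FALSE),
                   c("O6", "C6", "C5", "O5"))
})
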