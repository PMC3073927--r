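# Rotatable bonds, torsion library, fold reduction, torsion driving

test_that("rotor detection matches hand-derived counts", {
  counts <- c(butane = 1L, ethylbenzene = 1L, biphenyl = 1L,
              "tert-butylbenzene" = 1L, "para-difluorobenzene" = 0L,
              "sulfone-analogue" = 5L)
  for (name in names(counts)) {
    expect_equal(nrow(findRotatableBonds(fx(name)$mol)), unname(counts[name]),
                 info = name)
  }
  # butane: the central bond, not the methyl bonds
  bu <- findRotatableBonds(fx("butane")$mol)
  expect_equal(sort(c(bu$i, bu$j)), c(2, 3))
  # ethylbenzene: ring-CH2, the CH2-CH3 bond is excluded (methyl end has one
  # heavy neighbour)
  eb <- findRotatableBonds(fx("ethylbenzene")$mol)
  expect_true(7 %in% c(eb$i, eb$j) && any(c(eb$i, eb$j) %in% 1:6))
})

test_that("bonds to sp-hybridised atoms are never rotors", {
  # phenylacetylene-like toy: ring-C#C-H; the ring-Csp bond must be excluded
  eb <- fx("ethylbenzene")$mol
  atoms <- eb@atoms
  # rewrite the ethyl into an acetylene: C7 sp, C8 sp, drop two H of CH2/CH3
  atoms$hybrid[7:8] <- "sp"
  bonds <- eb@bonds
  bonds$order[bonds$i == 7 & bonds$j == 8 | bonds$i == 8 & bonds$j == 7] <- 3L
  m <- new("MoleculeGraph", atoms = atoms, bonds = bonds, title = "toy-yne",
           heavyIdx = eb@heavyIdx)
  rb <- findRotatableBonds(m)
  expect_false(any((rb$i == 1 & rb$j == 7) | (rb$i == 7 & rb$j == 1)))
})

test_that("torsion library parsing enforces the format contract", {
  lib <- loadTorsionLibrary()   # bundled default
  expect_s4_class(lib, "TorsionLibrary")
  expect_gte(nrow(lib@rules), 3)

  tmp <- tempfile()
  writeLines(c(
    "# comment line",
    "[!#1]~[CX4]-[CX4]~[!#1] 0 30 60 90 120 150 180 210 240 270 300 330",
    "",
    "[OX1]=[CX3]-[OX2][!#1]  0 180"
  ), tmp)
  lib2 <- loadTorsionLibrary(tmp)
  expect_equal(nrow(lib2@rules), 2)
  expect_equal(lib2@rules$angles[[1]], seq(0, 330, by = 30))
  expect_equal(lib2@rules$angles[[2]], c(0, 180))
  expect_equal(lib2@rules$priority, 1:2)

  bad <- tempfile(); writeLines("[!#1][CX4]-[CX4][!#1] 0 370", bad)
  expect_error(loadTorsionLibrary(bad), "\\[0, 360\\)")
  bad2 <- tempfile(); writeLines("[CX4]-[CX4] 0 120 240", bad2)
  expect_error(loadTorsionLibrary(bad2), "exactly 4 atoms")
  bad3 <- tempfile(); writeLines("[CX4][CX4][CX4][CX4]", bad3)
  expect_error(loadTorsionLibrary(bad3), "at least one angle")
})

test_that("rule priority: first match in file order wins", {
  bu <- fx("butane")
  bonds <- findRotatableBonds(bu$mol)
  tmp <- tempfile()
  writeLines(c(
    "[!#1][CX4]-[CX4][!#1]  0 120 240",
    "[#6][CX4]-[CX4][#6]    0 180"      # also matches, but later
  ), tmp)
  rs <- assignTorsionValues(bu$mol, bonds, loadTorsionLibrary(tmp), conf = bu$conf)
  expect_equal(rs@rotors[[1]]$angles, c(0, 120, 240))
})

test_that("unmatched bonds fall back to the 12-angle 30-degree grid", {
  bu <- fx("butane")
  bonds <- findRotatableBonds(bu$mol)
  tmp <- tempfile()
  writeLines("[OX1]=[CX3]-[OX2][!#1] 0 180", tmp)  # cannot match butane
  rs <- assignTorsionValues(bu$mol, bonds, loadTorsionLibrary(tmp), conf = bu$conf)
  expect_equal(rs@rotors[[1]]$angles, seq(0, 330, by = 30))
  expect_equal(totalConformers(rs), 12)
})

test_that("fold reduction implements the 2-fold/3-fold/multiplicative rule", {
  # tert-butylbenzene: sp2 ring end (2-fold) x sp3 tert-butyl end (3-fold)
  rs <- fxRotors("tert-butylbenzene")
  expect_equal(rs@rotors[[1]]$fold, 6L)
  expect_equal(rs@rotors[[1]]$angles, c(0, 30))

  # biphenyl: two sp2 ring ends -> fold 4, angles below 90
  rb <- fxRotors("biphenyl")
  expect_equal(rb@rotors[[1]]$fold, 4L)
  expect_equal(rb@rotors[[1]]$angles, c(0, 30, 60))

  # butane: CH2 ends have a single heavy neighbour each -> no fold
  ru <- fxRotors("butane")
  expect_equal(ru@rotors[[1]]$fold, 1L)
  expect_length(ru@rotors[[1]]$angles, 12)

  # ethylbenzene: ring end is 2-fold, CH2 end unfolded
  re <- fxRotors("ethylbenzene")
  expect_equal(re@rotors[[1]]$fold, 2L)
  expect_equal(re@rotors[[1]]$angles, seq(0, 150, by = 30))
})

test_that("fold reduction never empties or enlarges an angle set", {
  for (name in c("butane", "ethylbenzene", "tert-butylbenzene", "biphenyl",
                 "sulfone-analogue")) {
    f <- fx(name)
    bonds <- findRotatableBonds(f$mol)
    if (nrow(bonds) == 0) next
    pre <- assignTorsionValues(f$mol, bonds, conf = f$conf)
    post <- applyFoldReduction(f$mol, pre)
    for (k in seq_along(pre@rotors)) {
      expect_gte(length(post@rotors[[k]]$angles), 1)
      expect_lte(length(post@rotors[[k]]$angles), length(pre@rotors[[k]]$angles))
    }
    expect_lte(totalConformers(post), totalConformers(pre))
  }
})

test_that("fold-equivalent full-grid conformers have degenerate energies", {
  # the reduced grid loses no distinct-energy state: on tert-butylbenzene the
  # 12-angle grid partitions into groups of 6 with equal variable energy
  tb <- fx("tert-butylbenzene")
  bonds <- findRotatableBonds(tb$mol)
  pre <- assignTorsionValues(tb$mol, bonds, conf = tb$conf)
  r <- pre@rotors[[1]]
  cfs <- lapply(r$angles, function(a) setTorsion(tb$mol, tb$conf, r, a))
  ev <- variableEnergy(fxCtx("tert-butylbenzene"), cfs)
  groups <- split(ev, round(r$angles) %% 60)
  for (g in groups) expect_lt(max(g) - min(g), 1e-3)
})

test_that("setTorsion drives exactly and rigidly", {
  bu <- fx("butane")
  r <- fxRotors("butane")@rotors[[1]]
  circDiff <- function(a, b) min(abs(a - b), 360 - abs(a - b))
  for (target in c(0, 17.25, 60, 180, 273.9, 359.5)) {
    cf <- setTorsion(bu$mol, bu$conf, r, target)
    expect_lt(circDiff(measureTorsion(confCoords(cf), r$quad), target), 1e-6)
  }

  # setting 180 -> 60 -> 180 restores coordinates
  c1 <- setTorsion(bu$mol, bu$conf, r, 180)
  c3 <- setTorsion(bu$mol, setTorsion(bu$mol, c1, r, 60), r, 180)
  expect_lt(max(abs(confCoords(c1) - confCoords(c3))), 1e-6)

  # bond lengths unchanged by driving
  bl <- function(co) {
    apply(cbind(bu$mol@bonds$i, bu$mol@bonds$j), 1,
          function(p) sqrt(sum((co[p[1], ] - co[p[2], ])^2)))
  }
  cf <- setTorsion(bu$mol, bu$conf, r, 97)
  expect_lt(max(abs(bl(confCoords(cf)) - bl(confCoords(bu$conf)))), 1e-6)
})

test_that("independent rotors commute and leave other dihedrals alone", {
  su <- fx("sulfone-analogue")
  rs <- fxRotors("sulfone-analogue")
  # find two rotors with disjoint moving fragments
  pair <- NULL
  for (i in seq_len(rotorCount(rs) - 1)) {
    for (j in (i + 1):rotorCount(rs)) {
      if (length(intersect(rs@rotors[[i]]$moving, rs@rotors[[j]]$moving)) == 0) {
        pair <- c(i, j); break
      }
    }
    if (!is.null(pair)) break
  }
  expect_false(is.null(pair))
  ri <- rs@rotors[[pair[1]]]; rj <- rs@rotors[[pair[2]]]
  a <- setTorsion(su$mol, setTorsion(su$mol, su$conf, ri, 90), rj, 210)
  b <- setTorsion(su$mol, setTorsion(su$mol, su$conf, rj, 210), ri, 90)
  expect_lt(max(abs(confCoords(a) - confCoords(b))), 1e-6)

  # driving one rotor leaves every other rotor's dihedral unchanged
  base <- vapply(rs@rotors, function(r) measureTorsion(confCoords(su$conf), r$quad),
                 numeric(1))
  cf <- setTorsion(su$mol, su$conf, rs@rotors[[1]], 120)
  after <- vapply(rs@rotors, function(r) measureTorsion(confCoords(cf), r$quad),
                  numeric(1))
  circDiff <- function(a, b) pmin(abs(a - b), 360 - abs(a - b))
  expect_lt(max(circDiff(after[-1], base[-1])), 1e-6)
})

test_that("degenerate torsion frames are rejected", {
  bu <- fx("butane")
  r <- fxRotors("butane")@rotors[[1]]
  co <- confCoords(bu$conf)
  co[r$quad[1], ] <- co[r$quad[2], ] + 1.5 * (co[r$quad[2], ] - co[r$quad[3], ])
  expect_error(setTorsion(bu$mol, ConformerRecord(co), r, 60),
               "degenerate torsion frame")
})
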