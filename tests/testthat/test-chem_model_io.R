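# Molecule model, SDF I/O, symmetry classes and automorphisms

test_that("SDF reading perceives the fixtures correctly", {
  bu <- fx("butane")
  expect_s4_class(bu$mol, "MoleculeGraph")
  expect_equal(atomCount(bu$mol), 14)
  expect_equal(length(heavyAtoms(bu$mol)), 4)
  expect_equal(nrow(confCoords(bu$conf)), 14)
  expect_true(all(bu$mol@atoms$hybrid[heavyAtoms(bu$mol)] == "sp3"))

  eb <- fx("ethylbenzene")
  expect_equal(sum(eb$mol@atoms$inRing), 6)
  expect_equal(sum(eb$mol@bonds$aromatic), 6)
  expect_true(all(eb$mol@atoms$hybrid[1:6] == "sp2"))

  su <- fx("sulfone-analogue")
  expect_equal(length(heavyAtoms(su$mol)), 15)
  # hypervalent sulfone S is a rotatable centre, not linear
  sIdx <- which(su$mol@atoms$element == "S")
  expect_false(su$mol@atoms$hybrid[sIdx] == "sp")
})

test_that("multi-record files give one entry per record, bad records fail by number", {
  tmp <- tempfile(fileext = ".sdf")
  writeLines(c(makeFixture("butane"), makeFixture("ethylbenzene"),
               makeFixture("biphenyl")), tmp, sep = "")
  mols <- readMolecules(tmp)
  expect_length(mols, 3)
  expect_equal(vapply(mols, function(m) molTitle(m$mol), character(1)),
               c("butane", "ethylbenzene", "biphenyl"))

  # all-zero coordinates must be rejected: torsion driving needs 3D input
  zero <- strsplit(makeFixture("butane"), "\n")[[1]]
  atomLines <- 5:18
  zero[atomLines] <- sub("^.{30}", sprintf("%10.4f%10.4f%10.4f", 0, 0, 0),
                         zero[atomLines])
  tmp2 <- tempfile(fileext = ".sdf")
  writeLines(zero, tmp2)
  expect_error(readMolecules(tmp2), "3D")
})

test_that("formal charges survive reading and writing", {
  acetate <- c(
    "acetate", "  test", "",
    "  7  6  0  0  0  0  0  0  0  0999 V2000",
    "    1.1143    0.0479    0.0445 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.6330    0.0415    0.0207 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.1905    0.3354    1.1143 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.1439   -0.2582   -1.0948 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7325    0.3141    1.0348 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7352   -0.9445   -0.2172 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7352    0.7755   -0.6794 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  2  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "  1  6  1  0  0  0  0",
    "  1  7  1  0  0  0  0",
    "M  CHG  1   4  -1",
    "M  END",
    "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  writeLines(acetate, tmp)
  m <- readMolecules(tmp)[[1]]
  expect_equal(m$mol@atoms$charge, c(0L, 0L, 0L, -1L, 0L, 0L, 0L))

  out <- tempfile(fileext = ".sdf")
  writeConformers(out, m$mol, list(m$conf))
  back <- readMolecules(out)[[1]]
  expect_equal(back$mol@atoms$charge, m$mol@atoms$charge)
  expect_equal(back$mol@bonds$order, m$mol@bonds$order)
  expect_equal(confCoords(back$conf), confCoords(m$conf), tolerance = 1e-8)
})

test_that("conformer writing round-trips coordinates at SDF precision", {
  bu <- fx("butane")
  rs <- fxRotors("butane")
  ens <- lapply(c(60, 180, 300), function(a) {
    ConformerRecord(confCoords(setTorsion(bu$mol, bu$conf, rs@rotors[[1]], a)),
                    relEnergy = a / 100, index = a / 30)
  })
  tmp <- tempfile(fileext = ".sdf")
  writeConformers(tmp, bu$mol, ens)
  back <- readMolecules(tmp)
  expect_length(back, 3)
  expect_match(molTitle(back[[2]]$mol), "butane conformer 2")
  for (k in 1:3) {
    expect_lt(max(abs(confCoords(back[[k]]$conf) - confCoords(ens[[k]]))), 5e-5)
  }
  # the energy tag is written with 4 decimals
  expect_match(paste(readLines(tmp), collapse = "\n"), "Energy_rel_kcalmol>\n0.6000")
  expect_error(writeConformers(tempfile(), bu$mol, list()), "non-empty")
})

test_that("symmetry classes match brute-force automorphism orbits", {
  # tert-butylbenzene: the three methyl carbons share one class
  tb <- fx("tert-butylbenzene")
  cls <- computeSymmetryClasses(tb$mol)
  methyls <- which(tb$mol@atoms$element == "C")[8:10]  # heavy atoms 8..10
  pos <- match(methyls, heavyAtoms(tb$mol))
  expect_length(unique(cls@classId[pos]), 1)

  # butane: terminal pair and central pair, two distinct classes
  bu <- fx("butane")
  cb <- computeSymmetryClasses(bu$mol)@classId
  expect_equal(cb[1], cb[4])
  expect_equal(cb[2], cb[3])
  expect_false(cb[1] == cb[2])

  # orbits from exhaustive permutation search agree on every small fixture
  for (name in c("butane", "para-difluorobenzene", "ethylbenzene")) {
    m <- fx(name)$mol
    cls <- computeSymmetryClasses(m)@classId
    orb <- bruteOrbits(m)
    # class partition must refine to exactly the orbit partition here
    expect_equal(length(unique(cls)), length(unique(orb)), info = name)
    expect_true(all(tapply(orb, cls, function(x) length(unique(x))) == 1),
                info = name)
  }

  # 1,4-difluorobenzene: ring carbons fall into exactly 2 classes
  pd <- fx("para-difluorobenzene")
  cp <- computeSymmetryClasses(pd$mol)@classId
  expect_length(unique(cp[1:6]), 2)
})

test_that("symmetry classes are invariant under atom relabelling", {
  set.seed(7)
  for (name in c("butane", "ethylbenzene", "para-difluorobenzene", "sulfone-analogue")) {
    m <- fx(name)$mol
    n <- atomCount(m)
    ref <- sort(table(computeSymmetryClasses(m)@classId))
    for (rep in 1:3) {
      perm <- sample(n)
      pm <- permuteMolecule(m, perm)
      got <- sort(table(computeSymmetryClasses(pm)@classId))
      expect_equal(unname(as.integer(got)), unname(as.integer(ref)), info = name)
    }
  }
})

test_that("automorphism enumeration equals brute force on small graphs", {
  expect_length(enumerateAutomorphisms(fx("butane")$mol)@perms, 2)
  expect_length(enumerateAutomorphisms(benzeneGraph())@perms, 12)
  for (name in c("butane", "para-difluorobenzene", "ethylbenzene")) {
    m <- fx(name)$mol
    got <- enumerateAutomorphisms(m)
    ref <- bruteAutomorphisms(m)
    expect_false(got@truncated)
    expect_equal(length(got@perms), length(ref), info = name)
    key <- function(ps) sort(vapply(ps, paste, character(1), collapse = ","))
    expect_equal(key(got@perms), key(ref), info = name)
  }
})

test_that("automorphism cap truncates instead of blowing up", {
  expect_warning(a <- enumerateAutomorphisms(benzeneGraph(), cap = 5L),
                 "capped")
  expect_true(a@truncated)
  expect_length(a@perms, 5)
  expect_equal(a@perms[[1]], 1:6)  # identity always first
})
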