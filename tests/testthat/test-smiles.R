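test_that("organic-subset parsing fills implicit hydrogens from valence rules", {
  m <- parseSmiles("C")
  expect_equal(natoms(m), 1)
  expect_equal(nbonds(m), 0)
  expect_equal(atoms(m)$hcount, 4L)
  expect_false(atoms(m)$hexplicit)

  cases <- list(
    list(smi = "CC", h = c(3, 3)),
    list(smi = "CCO", h = c(3, 2, 1)),
    list(smi = "C=O", h = c(2, 0)),
    list(smi = "C#N", h = c(1, 0)),
    list(smi = "CCl", h = c(3, 0)),
    list(smi = "CS(=O)(=O)C", h = c(3, 0, 0, 0, 3)),  # sulfone: S valence 6
    list(smi = "C[N+](C)(C)C", h = c(3, 0, 3, 3, 3))
  )
  for (cs in cases) {
    expect_equal(atoms(parseSmiles(cs$smi))$hcount, as.integer(cs$h),
                 info = cs$smi)
  }
})

test_that("aromatic notation sets flags and ring-reserved valence", {
  m <- parseSmiles("c1ccccc1")
  expect_equal(natoms(m), 6)
  expect_equal(nbonds(m), 6)
  expect_true(all(atoms(m)$aromatic))
  expect_true(all(bonds(m)$aromatic))
  expect_equal(atoms(m)$hcount, rep(1L, 6))
  expect_equal(cyclomaticNumber(m), 1)

  pyr <- parseSmiles("c1ccncc1")
  expect_equal(atoms(pyr)$hcount[atoms(pyr)$element == "N"], 0L)
  # Kekule benzene is a distinct, non-aromatic input by design
  kek <- parseSmiles("C1=CC=CC=C1")
  expect_false(any(atoms(kek)$aromatic))
  expect_equal(sort(bonds(kek)$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_false(isTRUE(isSubstructure(m, kek)))
})

test_that("bracket atoms carry isotope, charge and explicit hydrogens", {
  m <- parseSmiles("[13CH4]")
  expect_equal(atoms(m)$isotope, 13L)
  expect_equal(atoms(m)$hcount, 4L)
  expect_equal(atoms(m)$charge, 0L)
  expect_true(atoms(m)$hexplicit)

  expect_equal(atoms(parseSmiles("[NH4+]"))$charge, 1L)
  expect_equal(atoms(parseSmiles("[O-]"))$charge, -1L)
  expect_equal(atoms(parseSmiles("[Fe+3]"))$charge, 3L)
  expect_equal(atoms(parseSmiles("[Fe+++]"))$charge, 3L)
  expect_equal(atoms(parseSmiles("[nH]"))$hcount, 1L)
  expect_true(atoms(parseSmiles("[nH]"))$aromatic)
  expect_equal(atoms(parseSmiles("[C@@H](C)(N)O"))$hcount[1], 1L)  # stereo discarded
})

test_that("ring closures, branches, %nn and fragments parse", {
  m <- parseSmiles("C1CCCCC1")
  expect_equal(nbonds(m), 6)
  expect_equal(nbonds(parseSmiles("C%12CCCCC%12")), 6)
  frag <- parseSmiles("CC.O")
  expect_equal(natoms(frag), 3)
  expect_equal(nbonds(frag), 1)
  branched <- parseSmiles("CC(C)(C)C")  # neopentane
  expect_equal(max(table(c(bonds(branched)$from, bonds(branched)$to))), 4)
  # double bond via ring closure symbol on either side
  expect_equal(bonds(parseSmiles("C=1CCCCC=1"))$order[6], 2L)
})

test_that("malformed SMILES raise positioned parse errors", {
  expect_error(parseSmiles("C(("), class = "smilesParseError")
  expect_error(parseSmiles("C)C"), class = "smilesParseError")
  expect_error(parseSmiles("C1CC"), class = "smilesParseError")  # unmatched ring
  expect_error(parseSmiles("C$C"), class = "smilesParseError")
  expect_error(parseSmiles("[Xx]"), class = "smilesParseError")
  expect_error(parseSmiles("[CH4"), class = "smilesParseError")
  expect_error(parseSmiles(""), class = "smilesParseError")
  err <- tryCatch(parseSmiles("CC$C"), error = identity)
  expect_match(conditionMessage(err), "position 3")
  # wildcard atoms are rejected, bare and bracketed
  expect_error(parseSmiles("C*"), class = "smilesParseError")
  expect_error(parseSmiles("[*]"), class = "smilesParseError")
  # hydrogens are not graph nodes
  expect_error(parseSmiles("[H][H]"), class = "smilesParseError")
})

test_that("serialization round-trips to an isomorphic graph", {
  for (nm in names(toy)) {
    m <- toy[[nm]]
    m2 <- parseSmiles(writeSmiles(m))
    expect_true(isIsomorphic(m, m2), info = nm)
    expect_equal(sort(atoms(m)$hcount), sort(atoms(m2)$hcount), info = nm)
  }
  # charged/isotope-labelled atoms force brackets and keep hydrogen counts
  chg <- parseSmiles("C[N+](C)(C)C")
  expect_true(isIsomorphic(chg, parseSmiles(writeSmiles(chg))))
})

test_that("generated molecules survive the SMILES round-trip", {
  cfg <- generatorConfig(seed = 7, nMolecules = 60)
  for (i in seq_len(60)) {
    m <- randomMolecule(cfg, i)
    m2 <- parseSmiles(writeSmiles(m))
    expect_equal(natoms(m2), natoms(m), info = i)
    expect_equal(nbonds(m2), nbonds(m), info = i)
    expect_equal(sort(atoms(m)$hcount), sort(atoms(m2)$hcount), info = i)
    expect_true(isIsomorphic(m, m2), info = i)
  }
})

test_that("SMILES files read with per-line failure accounting", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "c1ccccc1\tbenzene", "# comment", "",
               "C1CC\tbroken", "CC"), f)
  res <- readSmilesFile(f, quiet = TRUE)
  expect_equal(length(res$molecules), 3)
  expect_equal(res$failures, 1)
  expect_match(res$errors, "broken")
  expect_named(res$molecules, c("ethanol", "benzene", "L6"))

  empty <- tempfile(fileext = ".smi")
  writeLines(character(), empty)
  expect_equal(length(readSmilesFile(empty)$molecules), 0)
  expect_error(readSmilesFile(file.path(tempdir(), "nope.smi")), "cannot read")
})
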