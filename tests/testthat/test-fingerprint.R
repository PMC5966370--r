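test_that("atom-type features count distinct typed atoms with coverage", {
  f <- atomTypeFeatures(toy$ethanol)
  expect_equal(nrow(f), 2)
  expect_setequal(f$count, c(2L, 1L))
  expect_setequal(unlist(f$coverage), 1:3)

  f <- atomTypeFeatures(toy$benzene)
  expect_equal(nrow(f), 1)
  expect_equal(f$count, 6L)
  expect_equal(f$coverage[[1]], 1:6)

  # charge differentiates the type tuple
  h1 <- atomTypeFeatures(parseSmiles("[NH4+]"))$hash
  h2 <- atomTypeFeatures(parseSmiles("N"))$hash
  expect_false(h1 == h2)
  # aromatic flag differentiates too
  expect_false(atomTypeFeatures(parseSmiles("c1ccccc1"))$hash ==
               atomTypeFeatures(parseSmiles("C"))$hash)
})

test_that("subgraph enumeration matches the brute-force subset oracle", {
  expect_length(enumerateSubgraphs(toy$ethane, 7), 1)
  expect_length(enumerateSubgraphs(toy$propane, 7), 3)
  expect_length(enumerateSubgraphs(toy$benzene, 7), 31)

  cfg <- generatorConfig(seed = 23, nMolecules = 40, atomCountRange = c(3L, 9L),
                         ringProbability = 0.5)
  for (i in seq_len(40)) {
    m <- randomMolecule(cfg, i)
    if (nbonds(m) > 10) next
    for (mb in c(3L, 7L)) {
      got <- enumerateSubgraphs(m, mb)
      want <- bruteSubgraphs(m, mb)
      expect_equal(subgraphKey(got), subgraphKey(want),
                   info = sprintf("mol %d maxBonds %d", i, mb))
    }
  }
})

test_that("tree hash is invariant under atom relabelling", {
  set.seed(101)
  cfg <- generatorConfig(seed = 31, nMolecules = 50, ringProbability = 0.5)
  checked <- 0
  for (i in seq_len(50)) {
    m <- randomMolecule(cfg, i)
    if (nbonds(m) < 2) next
    subs <- enumerateSubgraphs(m, 5)
    sub <- subs[[sample(length(subs), 1)]]
    perm <- sample(natoms(m))
    mp <- permuteAtoms(m, perm)
    # find the image of the subgraph's bonds in the permuted molecule
    b <- bonds(m); bp <- bonds(mp)
    keyP <- paste(bp$from, bp$to)
    img <- vapply(sub, function(k) {
      x <- perm[b$from[k]]; y <- perm[b$to[k]]
      match(paste(min(x, y), max(x, y)), keyP)
    }, integer(1))
    expect_equal(treeHash(mp, img), treeHash(m, sub), info = i)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("tree hash separates non-isomorphic subgraphs and honours contracts", {
  cc <- parseSmiles("CC"); cn <- parseSmiles("CN")
  expect_false(treeHash(cc, 1L) == treeHash(cn, 1L))
  # bond order and aromatic flag enter the hash
  expect_false(treeHash(parseSmiles("C=C"), 1L) == treeHash(cc, 1L))
  # ring hashed identically from any starting rotation: naphthalene's two
  # isomorphic rings hash equal even though their atom indices differ
  naph <- sssr(toy$naphthalene)
  expect_equal(treeHash(toy$naphthalene, naph[[1]]$bonds, "ring"),
               treeHash(toy$naphthalene, naph[[2]]$bonds, "ring"))
  # contract violations
  expect_error(treeHash(toy$biphenyl, c(1L, 8L)), "disconnected")
  expect_error(treeHash(toy$naphthalene, seq_len(11)), "more than one ring")
})

test_that("multiplicity encoding gives every power of 2 up to the count", {
  expect_equal(encodeMultiplicity(1), 1L)
  expect_equal(encodeMultiplicity(5), c(1L, 2L, 4L))
  expect_equal(encodeMultiplicity(8), c(1L, 2L, 4L, 8L))
  expect_error(encodeMultiplicity(0), ">= 1")
})

test_that("benzene fingerprint has the expected family structure", {
  fp <- fingerprint(toy$benzene)
  feats <- fp@features
  expect_equal(sum(feats$kind == "atom_type"), 1)
  expect_equal(sum(feats$kind == "ring"), 1)
  # 31 subgraphs collapse to 6 shapes: 5 paths (count 6) + the ring (count 1)
  sg <- feats[feats$kind == "subgraph", ]
  expect_equal(nrow(sg), 6)
  expect_setequal(sg$count, c(6L, 6L, 6L, 6L, 6L, 1L))
  b <- featureBits(fp)
  expect_equal(sum(b$kind == "atom_type"), 3)   # tiers 1,2,4 of 6 carbons
  expect_equal(sum(b$kind == "ring"), 1)
  expect_equal(sum(b$kind == "subgraph"), 16)   # 5 shapes x {1,2,4} + ring x {1}
  expect_false(anyDuplicated(b$id) > 0)
  # empty molecule gives an empty feature set
  expect_equal(nrow(featureBits(fingerprint(Molecule()))), 0)
})

test_that("fingerprints satisfy substructure closure on constructed pairs", {
  cfg <- generatorConfig(seed = 41, nMolecules = 60, ringProbability = 0.4)
  for (i in seq_len(60)) {
    m <- randomMolecule(cfg, i)
    q <- randomSubquery(m, seed = i * 3 + 1)
    for (gs in c(3L, 7L)) {
      bm <- featureIds(fingerprint(m, fingerprintParams(gs)))
      fq <- fingerprint(q, fingerprintParams(gs))
      # ring bits are exempt: the smallest-ring set is not monotone under
      # extension, which is exactly why queries never screen with them
      bq <- featureBits(fq)
      bq <- bq$id[bq$kind != "ring"]
      expect_true(all(bq %in% bm), info = sprintf("mol %d gs %d", i, gs))
    }
  }
})

test_that("fingerprint bits grow monotonically with graphSize", {
  cfg <- generatorConfig(seed = 53, nMolecules = 25)
  for (i in seq_len(25)) {
    m <- randomMolecule(cfg, i)
    prev <- featureIds(fingerprint(m, fingerprintParams(1)))
    for (gs in 2:8) {
      cur <- featureIds(fingerprint(m, fingerprintParams(gs)))
      expect_true(all(prev %in% cur), info = sprintf("mol %d gs %d", i, gs))
      prev <- cur
    }
  }
})

test_that("isomorphic molecules fingerprint identically", {
  set.seed(77)
  cfg <- generatorConfig(seed = 61, nMolecules = 20, ringProbability = 0.5)
  for (i in seq_len(20)) {
    m <- randomMolecule(cfg, i)
    mp <- permuteAtoms(m, sample(natoms(m)))
    expect_setequal(featureIds(fingerprint(m)), featureIds(fingerprint(mp)))
  }
})
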