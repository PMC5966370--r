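test_that("keyword encoding is the big-endian base64 split of 36 bits", {
  expect_equal(encodeKeyword(0), "AAAAAA")
  expect_equal(encodeKeyword(1), "AAAAAB")
  expect_equal(encodeKeyword(2^36 - 1), "//////")
  expect_equal(encodeKeyword(64), "AAAABA")
  expect_error(encodeKeyword(2^36), "36-bit")
  expect_error(encodeKeyword(-1), "36-bit")

  set.seed(99)
  vals <- unique(floor(runif(5000, 0, 2^36)))
  kws <- encodeKeyword(vals)
  expect_true(all(nchar(kws) == 6))
  expect_false(anyDuplicated(kws) > 0)
  expect_equal(decodeKeyword(kws), vals)
})

toyIndex <- buildIndex(toy)

test_that("posting lists are complete and correct on the toy corpus", {
  idx <- toyIndex
  expect_equal(manifest(idx)$n, length(toy))
  # benzene's SSSR ring keyword posts exactly the aromatic 6-ring compounds
  ringBit <- featureBits(fingerprint(toy$benzene))
  ringBit <- ringBit$id[ringBit$kind == "ring"]
  # (pyridine's ring embeds an N, so it is a different shape; naphthalene's
  # two rings are plain aromatic 6-rings and do count)
  aromatic6 <- c("benzene", "toluene", "biphenyl", "naphthalene", "phenol")
  want <- sort(match(aromatic6, names(toy)) - 1L)
  expect_equal(idx@postings[[encodeKeyword(ringBit)]], want)
  # index completeness: every bit of every compound posts its ordinal
  for (i in seq_along(toy)) {
    for (kw in encodeKeyword(featureIds(fingerprint(toy[[i]])))) {
      expect_true((i - 1L) %in% idx@postings[[kw]],
                  info = paste(names(toy)[i], kw))
    }
  }
  # duplicates under distinct ids share every keyword
  dup <- buildIndex(list(a = toy$ethanol, b = toy$ethanol))
  for (kw in ls(dup@postings)) expect_equal(dup@postings[[kw]], c(0L, 1L))
  expect_error(buildIndex(list(toy$ethanol, toy$ethane)), "uniquely named")
  empty <- buildIndex(list())
  expect_equal(manifest(empty)$n, 0)
  expect_length(vocabulary(empty), 0)
})

test_that("candidate retrieval intersects posting lists anti-monotonically", {
  idx <- toyIndex
  fpB <- fingerprint(toy$benzene)
  # every benzene bit is shared exactly by the compounds embedding a plain
  # aromatic 6-ring
  expect_equal(candidates(idx, featureIds(fpB)),
               sort(match(c("benzene", "toluene", "biphenyl", "naphthalene",
                            "phenol"), names(toy)) - 1L))
  # on the minimal three-compound corpus only benzene itself survives
  idx3c <- buildIndex(list(ethane = toy$ethane, benzene = toy$benzene,
                           ethanol = toy$ethanol))
  expect_equal(candidates(idx3c, featureIds(fpB)), 1L)
  expect_equal(candidates(idx, numeric()), 0:(length(toy) - 1L))
  # unseen keyword empties the result
  unseen <- 123456789
  expect_length(candidates(idx, unseen), 0)
  expect_length(candidates(idx, c(featureIds(fpB), unseen)), 0)
  # growing the bit set never grows the candidate set
  ids <- featureIds(fpB)
  prev <- candidates(idx, numeric())
  for (k in seq_along(ids)) {
    cur <- candidates(idx, ids[seq_len(k)])
    expect_true(all(cur %in% prev), info = k)
    prev <- cur
  }
})

test_that("occurrence is document frequency over corpus size", {
  idx <- buildIndex(list(a = toy$ethane, b = toy$benzene,
                         c = toy$ethanol, d = toy$toluene))
  tab <- occurrenceTable(idx)
  ccBit <- featureBits(fingerprint(toy$ethane))
  ccBit <- ccBit$id[ccBit$kind == "subgraph"][1]      # the C-C bond shape
  # ethane and ethanol have a plain C-C bond; toluene's methyl bonds to an
  # aromatic carbon, which is a different shape
  expect_equal(occurrence(tab, ccBit), 2 / 4)
  expect_equal(occurrence(tab, 42), 0)                 # unseen bit
  ringBit <- featureBits(fingerprint(toy$benzene))
  ringBit <- ringBit$id[ringBit$kind == "ring"]
  expect_equal(occurrence(tab, ringBit), 2 / 4)
  emptyTab <- occurrenceTable(buildIndex(list()))
  expect_error(occurrence(emptyTab, 42), "empty corpus")
})

test_that("the index round-trips through its on-disk format", {
  dir <- file.path(tempdir(), "toyidx")
  saveIndex(toyIndex, dir)
  idx2 <- loadIndex(dir)
  expect_equal(manifest(idx2)[c("graphSize", "n", "ids")],
               manifest(toyIndex)[c("graphSize", "n", "ids")])
  expect_equal(vocabulary(idx2), vocabulary(toyIndex))
  set.seed(7)
  vocab <- vocabulary(toyIndex)
  for (r in 1:20) {
    bits <- decodeKeyword(sample(vocab, sample(1:4, 1)))
    expect_equal(candidates(idx2, bits), candidates(toyIndex, bits), info = r)
  }
  # stored molecules still verify
  expect_true(isSubstructure(toy$benzene,
                             storedMolecule(idx2, match("toluene", names(toy)) - 1L)))
})

test_that("corrupt or incompatible on-disk indices fail loudly", {
  dir <- file.path(tempdir(), "toyidx2")
  saveIndex(toyIndex, dir)
  # truncated postings -> integrity error, never wrong answers
  pf <- file.path(dir, "postings.bin")
  raw <- readBin(pf, "raw", file.info(pf)$size)
  writeBin(raw[seq_len(length(raw) - 5)], pf)
  expect_error(loadIndex(dir), "integrity")
  # version mismatch -> explicit incompatibility error
  dir2 <- file.path(tempdir(), "toyidx3")
  saveIndex(toyIndex, dir2)
  mf <- jsonlite::read_json(file.path(dir2, "manifest.json"))
  mf$formatVersion <- 99
  jsonlite::write_json(mf, file.path(dir2, "manifest.json"), auto_unbox = TRUE)
  expect_error(loadIndex(dir2), "incompatible")
  expect_error(loadIndex(file.path(tempdir(), "no-such-index")), "manifest")
})

test_that("a graph-size mismatch warns and the manifest wins", {
  idx3 <- buildIndex(toy, fingerprintParams(3))
  expect_warning(
    res <- searchSubstructure(idx3, toy$benzene, params = fingerprintParams(7)),
    "overridden by index manifest")
  expect_true((match("benzene", names(toy)) - 1L) %in% res@verified)
})
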