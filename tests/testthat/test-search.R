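toyIdx <- buildIndex(toy)
toyTab <- occurrenceTable(toyIdx)

test_that("subsumption reduction keeps top tiers and maximal subgraphs", {
  # multiplicity tiers collapse to the highest
  fpB <- fingerprint(toy$benzene)
  red <- subsumptionReduce(fpB)
  rb <- featureBits(red)
  expect_false(any(rb$kind == "ring"))
  at <- rb[rb$kind == "atom_type", ]
  expect_equal(nrow(at), 1)
  expect_equal(at$tier, 4L)                 # tiers {1,2} subsumed by 4
  # propane: both C-C bond bits (tiers 1 and 2 of the one shape) are
  # subsumed by the 2-bond path, whose instance holds two C-C copies; the
  # carbon count tiers stay (counts are independent information)
  fpP <- fingerprint(toy$propane)
  rp <- featureBits(subsumptionReduce(fpP))
  sg <- rp[rp$kind == "subgraph", ]
  expect_equal(nrow(sg), 1)
  expect_equal(sg$count, 1L)                # the full 2-bond path
  expect_equal(sg$hash, treeHash(toy$propane, c(1L, 2L)))
  expect_true(2 %in% rp$tier[rp$kind == "atom_type"])
  # a lone atom-type bit has nothing to subsume it
  fpO <- fingerprint(parseSmiles("O"))
  ro <- featureBits(subsumptionReduce(fpO))
  expect_equal(nrow(ro), 1)
  expect_equal(ro$kind, "atom_type")
})

test_that("reduction never changes the candidate set", {
  # against the tier-pruned, ring-free bit set the reduced set screens the
  # same compounds: every dropped bit is implied by a retained one
  mols <- c(toy, list(q1 = parseSmiles("CCC(C)O"), q2 = parseSmiles("c1ccncc1C")))
  for (nm in names(mols)) {
    fs <- fingerprint(mols[[nm]])
    bits <- featureBits(fs)
    bits <- bits[bits$kind != "ring", ]
    key <- paste(bits$kind, bits$hash)
    top <- unlist(lapply(split(seq_len(nrow(bits)), key),
                         function(ix) ix[which.max(bits$tier[ix])]))
    tierPruned <- bits$id[top]
    reduced <- featureIds(subsumptionReduce(fs))
    expect_true(all(reduced %in% tierPruned), info = nm)
    expect_equal(candidates(toyIdx, reduced), candidates(toyIdx, tierPruned),
                 info = nm)
  }
})

test_that("bit selection follows the covering-counter trace", {
  # hand-built feature sets: hashes are arbitrary distinct ids
  mkfs <- function(ids, coverage, atoms) {
    feats <- data.frame(kind = "subgraph", hash = ids,
                        count = 1L, coverage = I(coverage),
                        instances = I(rep(list(list(1L)), length(ids))))
    bits <- data.frame(id = ids, kind = "subgraph", hash = ids,
                       tier = 1L, count = 1L)
    new("FeatureSet", features = feats, bits = bits, atoms = atoms,
        graphSize = 7L)
  }
  mkTab <- function(ids, occ, total = 100L) {
    new("OccurrenceTable",
        frequency = stats::setNames(occ * total, encodeKeyword(ids)),
        total = total)
  }
  expect_equal(selectBits(fingerprint(Molecule()), toyTab)$selectedBits,
               numeric())
  # maxBits = 1: only the rarest bit covering atom 1 survives
  ids <- c(11, 12, 13)
  fs <- mkfs(ids, list(1L, 1L, 1L), atoms = 1L)
  plan <- selectBits(fs, mkTab(ids, c(0.1, 0.2, 0.3)),
                     selectionParams(minCover = 2, maxBits = 1))
  expect_equal(plan$selectedBits, 11)
  expect_equal(plan$discardedSelected, 2L)
  # minCover = 2 on two atoms: the two rarest kept, the third redundant
  fs2 <- mkfs(ids, list(c(1L, 2L), c(1L, 2L), c(1L, 2L)), atoms = 1:2)
  plan2 <- selectBits(fs2, mkTab(ids, c(0.05, 0.10, 0.20)),
                      selectionParams(minCover = 2, maxBits = 32))
  expect_equal(plan2$selectedBits, c(11, 12))
  # occurrence ties break by ascending FeatureId
  plan3 <- selectBits(fs2, mkTab(ids, c(0.2, 0.2, 0.2)),
                      selectionParams(minCover = 1, maxBits = 32))
  expect_equal(plan3$selectedBits, 11)
  # unseen bits sort first: maximal filtering power
  plan4 <- selectBits(fs, mkTab(ids, c(0.5, 0.0, 0.4)),
                      selectionParams(minCover = 1, maxBits = 32))
  expect_equal(plan4$selectedBits[1], 12)
})

test_that("search on the toy corpus verifies exactly the true matches", {
  idx <- buildIndex(list(ethane = toy$ethane, benzene = toy$benzene,
                         ethanol = toy$ethanol, toluene = toy$toluene))
  res <- searchSubstructure(idx, toy$benzene)
  expect_equal(res@verified, c(1L, 3L))        # benzene, toluene
  expect_true(all(res@verified %in% res@candidates))
  # a query identical to an indexed compound always verifies itself
  for (nm in names(toy)) {
    r <- suppressWarnings(searchSubstructure(toyIdx, toy[[nm]]))
    expect_true((match(nm, names(toy)) - 1L) %in% r@verified, info = nm)
  }
  # an element absent from the corpus screens everything out
  rS <- searchSubstructure(toyIdx, parseSmiles("CBr"))
  expect_length(rS@candidates, 0)
  expect_length(rS@verified, 0)
  # a single-atom query screens on its atom-type bit alone
  rO <- searchSubstructure(toyIdx, parseSmiles("O"))
  expect_setequal(rO@verified,
                  match(c("ethanol", "phenol", "aceticAcid"), names(toy)) - 1L)
  # only a featureless (empty) query falls back to a verified full scan
  expect_warning(rE <- searchSubstructure(toyIdx, Molecule()), "full scan")
  expect_equal(rE@candidates, 0:(length(toy) - 1L))
})

test_that("screening statistics follow their definitions", {
  res <- new("SearchResult", candidates = 0:9, verified = 0:7,
             undecided = integer(), corpusSize = 98L, plan = list())
  st <- screeningStats(res)
  expect_equal(st[["precision"]], 0.8)
  expect_equal(st[["fpr"]], 2 / 90)
  # no false positives
  res2 <- new("SearchResult", candidates = 0:7, verified = 0:7,
              undecided = integer(), corpusSize = 98L, plan = list())
  expect_equal(screeningStats(res2)[["fpr"]], 0)
  # empty screening: precision 1 by convention
  res3 <- new("SearchResult", candidates = integer(), verified = integer(),
              undecided = integer(), corpusSize = 98L, plan = list())
  expect_equal(screeningStats(res3)[["precision"]], 1)
  expect_equal(screeningStats(res3)[["fpr"]], 0)
})

test_that("query evaluation is deterministic and selection-consistent", {
  queries <- list(benzene = toy$benzene, ethanol = toy$ethanol,
                  co = parseSmiles("CO"), pyridine = toy$pyridine,
                  ring7 = toy$cycloheptane)
  ev1 <- evaluateQueries(toyIdx, queries)
  ev2 <- evaluateQueries(toyIdx, queries)
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1$perQuery), 5)
  expect_true(all(ev1$perQuery$fpr >= 0 & ev1$perQuery$fpr <= 1))
  expect_true(all(ev1$perQuery$precision >= 0 & ev1$perQuery$precision <= 1))
  # screening with all reduced bits is at least as sharp as with a selection
  evAll <- evaluateQueries(toyIdx, queries,
                           selectionParams(selectEnabled = FALSE))
  expect_true(all(evAll$perQuery$fpr <= ev1$perQuery$fpr + 1e-12))
  expect_equal(evAll$perQuery$verified, ev1$perQuery$verified)
})

test_that("the selection cap bounds the plan size", {
  big <- randomMolecule(generatorConfig(seed = 3, atomCountRange = c(16L, 20L)), 1)
  fs <- subsumptionReduce(fingerprint(big))
  for (mb in c(1L, 4L, 32L)) {
    plan <- selectBits(fs, toyTab, selectionParams(maxBits = mb))
    expect_lte(length(plan$selectedBits), mb)
  }
  # with generous limits the plan equals the reduced fingerprint
  planAll <- selectBits(fs, toyTab,
                        selectionParams(minCover = 10000L, maxBits = 100000L))
  expect_setequal(planAll$selectedBits, featureIds(fs))
  expect_error(selectionParams(minCover = 0), "minCover")
})
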