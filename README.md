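# MolScreen

Chemical substructure search as a self-contained R package: substructural
fingerprint screening over an inverted keyword index, followed by exact
VF2-style subgraph-isomorphism verification. It is aimed at
cheminformatics work at desk scale — building a searchable index over a
few thousand SMILES records, studying screening behaviour (precision,
false positive rate, parameter effects), or just deciding whether one
molecular fragment occurs inside another — without a database cartridge
or any external engine.

## The method

Deciding whether a query fragment *Q* is a subgraph of a molecule *M* is
NP-complete, so a search engine never matches the whole database. Instead
each compound is *fingerprinted* into a set of substructural bits:

* **atom types** — one bit family per distinct (element, charge,
  aromatic) tuple, with occurrence counts;
* **SSSR rings** — each smallest ring (minimum cycle basis, B − A + C
  rings) hashed as a shape;
* **connected subgraphs** — every connected subgraph with at most
  `graphSize` (default 7) bonds and at most one ring, canonicalized by a
  tree hash (strip leaves with a sorted combiner; hash a remaining ring
  at its lexically minimal rotation over both directions).

Multiplicity is tier-encoded: a feature occurring *c* times sets a bit
for every power of two ≤ *c* ("occurs at least *p* times"). Each bit is
folded to a 36-bit integer and stored as a 6-character base64 keyword
whose posting list holds the ordinals of the compounds containing it.

Because every bit present in a fragment is present in every extension of
that fragment (the substructural closure property), intersecting the
posting lists of the query's bits yields a candidate set with **no false
negatives**; VF2 verification then removes the false positives. Query
fingerprints are first reduced losslessly (subsumed bits dropped) and
then thinned by a filtering-power selection: bits are visited from rarest
to most common and kept only while some covered query atom has fewer than
`minCover` (default 2) selected bits, with a hard cap of `maxBits`
(default 32). Screening quality is reported as precision = TP / screened
positives and FPR = FP / negatives.

The methods vignette (`vignettes/substructure-screening.Rmd`) documents
the model, the design decisions and their rationale in full.

## Worked example

```r
library(MolScreen)

corpus <- toyCorpus()              # 13 named small molecules
idx <- buildIndex(corpus)
idx
#> InvertedIndex: 13 compounds, 318 keywords (graphSize = 7)

res <- searchSubstructure(idx, parseSmiles("c1ccccc1"))
res
#> SearchResult: 5 candidates, 5 verified, 0 undecided (corpus 13)
#>   precision = 1, FPR = 0
manifest(idx)$ids[res@verified + 1]
#> [1] "benzene"     "toluene"     "biphenyl"    "naphthalene" "phenol"
```

All five compounds containing an aromatic six-ring were screened in, and
every candidate verified — on this corpus the benzene query screens
perfectly (precision 1, FPR 0). The fingerprint behind it:

```r
fp <- fingerprint(parseSmiles("c1ccccc1"))
fp
#> FeatureSet: 8 base features, 20 bits (graphSize = 7)
#>   families: atom_type=1, ring=1, subgraph=6
```

One aromatic-carbon atom type (count 6 → tiers 1, 2, 4), one SSSR ring,
and six subgraph shapes (paths of 1–5 bonds plus the ring itself). The
exact matcher is exposed directly as well:

```r
countEmbeddings(parseSmiles("c1ccccc1"), parseSmiles("c1ccccc1"))
#> [1] 12
```

— the twelve automorphic images of a benzene ring, the figure that makes
repeated-ring queries expensive for every backtracking matcher.

A command-line interface wraps the same functions:

```sh
molscreen index build --input corpus.smi --out IDX --graph-size 7
molscreen search --index IDX --query "c1ccccc1" --stats
molscreen match --query "c1ccccc1" --target "Cc1ccccc1"   # prints: true
molscreen fixtures generate --seed 1 --n 100 --out corpus.smi
molscreen inspect features --smiles "CCO"
```

(`molscreen` is installed at `inst/exec/molscreen`; run it via
`Rscript $(Rscript -e 'cat(system.file("exec","molscreen",package="MolScreen"))')`
or symlink it onto your PATH.)

Note one deliberate semantic choice: aromaticity is read from the input
notation only. Kekulé-written (`C1=CC=CC=C1`) and aromatic-written
(`c1ccccc1`) benzene are different structures here and do not
cross-match; normalize inputs consistently.

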