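---
title: "Substructure screening with substructural fingerprints: model and design"
author: "MolScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure screening with substructural fingerprints: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MolScreen)
```

## The problem

Substructure search asks, for a query fragment $Q$ and a compound database
$\{M_1, \dots, M_N\}$, which compounds contain $Q$ as a subgraph. Subgraph
isomorphism is NP-complete, so answering by matching every compound is
hopeless at database scale. The standard architecture is therefore
*screen-then-verify*: a cheap fingerprint test removes compounds that
provably cannot match, and an exact matcher (here, a VF2-style backtracking
search) verifies only the survivors.

The screen is sound when the fingerprint is *substructural*: every bit set
in a fragment's fingerprint must also be set in the fingerprint of any
molecule containing that fragment. Under that closure property, screening
can produce false positives (removed later by verification) but never false
negatives — no true match is ever lost. Zero false negatives is the
property this package treats as non-negotiable; the test suite verifies it
against a brute-force full-scan oracle across hundreds of randomized
corpus/query trials and all parameter combinations it ships with.

## The fingerprint

A molecule is an attributed graph: atoms carry element, formal charge,
isotope, an aromatic flag and a hydrogen count (hydrogens are counts, not
nodes); bonds carry an order in $\{1,2,3\}$ and an aromatic flag. Three
feature families are extracted:

1. **Atom types** — one base feature per distinct
   (element, charge, aromatic) tuple, with its occurrence count.
2. **SSSR rings** — the molecule's Smallest Set of Smallest Rings, each
   ring hashed as a shape; isomorphic rings collapse into one feature
   counted with multiplicity.
3. **Connected subgraphs** — every connected subgraph with $1 \le b \le$
   `graphSize` bonds and at most one ring, collapsed by a canonical tree
   hash. The one-ring cap keeps canonicalization cheap: strip leaves
   layer by layer, folding each leaf's accumulated hash and incident bond
   label into its neighbour through a sorted (order-independent) combiner;
   an acyclic subgraph terminates at its 1- or 2-atom centre, a one-ring
   subgraph terminates at the ring, which is hashed at its lexically
   minimal rotation, taken over both traversal directions so the hash is a
   genuine isomorphism invariant.

Multiplicity is encoded in tiers: a feature occurring $c$ times sets one
bit per power of two $p \le c$, read as "occurs at least $p$ times". A
fragment occurring $c_Q$ times in the query occurs at least $c_Q$ times in
any extension, so tier bits respect closure.

Every bit is a 36-bit integer — a fixed 64-bit avalanche mix
(splitmix-style) of the structural hash, the family tag and the tier,
truncated to 36 bits. Hash collisions merge two features into one bit;
that can only ever merge posting lists, i.e. create extra screening false
positives, never false negatives. For indexing, the 36-bit value is split
big-endian into six 6-bit groups mapped through the RFC 4648 base64
alphabet, giving the fixed-width 6-character keyword the inverted index
stores as a term.

### What is deliberately left out of feature labels

The matcher compares isotopes only when the query atom specifies one, and
hydrogen counts only when they were bracket-written in the query. A label
component that the matcher enforces only conditionally must not enter the
fingerprint: a plain-carbon query must be able to reach a compound whose
only carbon is $^{13}$C, so isotopes and hydrogen counts appear in no
feature label. Charges and aromatic flags are compared unconditionally
under the default matching options and are part of every label. The cost
is screening power (an isotope-specific query screens on its
isotope-agnostic bits and relies on verification), never correctness.

### Ring bits never screen on the query side

The SSSR is not monotone under graph extension. Add a chord across a
6-ring: the extended molecule's smallest rings are two shorter cycles, and
the plain 6-ring — the whole SSSR of the chord-free query — is no longer
among them. A query-side ring bit can therefore be absent from a true
match's fingerprint. For that reason query reduction drops ring-kind bits
outright before screening. Ring shapes up to `graphSize` bonds still
screen, because they are also enumerated as subgraph-kind features (with a
different family tag); ring features remain first-class in fingerprints
and in the index vocabulary. Large rings beyond `graphSize` bonds
contribute no screening power and are caught by verification.

## SSSR

`sssr()` returns exactly $B - A + C$ rings (bonds − atoms + components), a
minimum cycle basis: candidate cycles are collected Horton-style (one
shortest cycle per vertex/edge pair, plus the fundamental cycles of a BFS
forest as a completeness fallback), ordered by (length, lexicographically
smallest sorted bond-index set), and accepted greedily under GF(2)
independence until the basis is full. The lexical tie-break makes the
output deterministic for a fixed atom ordering. Pure edge-coverage
greediness is insufficient on rank-deficient cages (the cube graph's edges
are covered by four faces, yet the basis needs five); the GF(2) test is
what guarantees the count.

## Query reduction and bit selection

Querying intersects posting lists, and frequent keywords make that
expensive, so the query fingerprint is thinned in two steps.

**Subsumption (lossless for screening).** (0) ring bits are dropped, as
above; (a) within each base feature only the highest tier survives — its
posting list is contained in every lower tier's; (b) a subgraph shape
whose surviving tier is $p$ is dropped when one instance of another
subgraph feature contains at least $p$ distinct instances of the shape
(any compound holding the container holds $p$ copies of the contained
shape; for $p = 1$ this is plain bond-set containment); (c) a
single-occurrence atom-type bit is dropped when its atom lies inside a
retained subgraph feature, whose hash embeds that atom's label. Every
drop is justified by a posting-list containment, so the candidate set is
provably unchanged; the suite asserts that equality on every toy and
generated query.

**Statistical selection (lossy by design).** Each query atom gets a
covering counter starting at zero. Bits are visited in descending
filtering power — ascending corpus occurrence, ties broken by ascending
bit value, with never-seen bits first (an empty posting list screens out
everything). A bit is kept iff some atom it covers has a counter below
`minCover`, whereupon all its covered atoms' counters are incremented; a
hard stop applies after `maxBits` kept bits (the cap is checked before
adding, making it a strict bound on plan size). Selection trades
screen-out for fewer posting lists; it can add false positives but, by the
closure argument, never false negatives.

A query whose reduced fingerprint is empty (an empty molecule is the only
such case here) falls back to full-scan verification with a warning.

## Matching semantics

Verification is a VF2-style backtracking search over injective atom
mappings, implemented in C++ with a precomputed match order (frontier
first, then by descending degree — a heuristic that never changes
results). Compatibility is a declared convention: elements equal; charges
equal (default `chargeSensitive = TRUE`); isotopes equal only when the
query specifies one; aromatic flags equal; target hydrogen count at least
the query's when the query's was bracket-specified. An aromatic query
bond requires an aromatic target bond; a non-aromatic query bond requires
a non-aromatic target bond of equal order. Multi-fragment queries need
one global injective mapping, so $n$ separate benzene rings do not match a
fused system that can only host $n-1$ disjoint rings.

Aromaticity is read from the input notation only (lowercase atoms, `:`
bonds); no Hückel-style perception is attempted. Kekulé-written and
aromatic-written benzene are distinct structures here and do not
cross-match; inputs must be written consistently. This is a real semantic
difference from cartridges that normalize aromaticity, and it is the main
caveat when comparing results with such systems.

Worst-case subgraph matching is exponential, and some inputs genuinely
explode (odd-cycle queries against certain degenerate fused systems). An
optional state limit turns such searches into an explicit "undecided"
outcome — reported separately by the search layer, never silently treated
as a non-match. The default leaves the limit unset (exact behaviour).

## The index

The inverted index is a bespoke single-directory store rather than an
external text-search engine, but it honours the same keyword contract
(6-character base64 terms, one posting list per term) so an engine-backed
variant could be swapped in behind the same interface. On disk:
`manifest.json` (format version, `graphSize`, corpus size, the 0-based
ordinal → identifier mapping, build-time parse-failure count), `vocab.tsv`
(sorted keywords with byte offsets and document frequencies),
`postings.bin` (per-keyword varint-encoded deltas of strictly increasing
ordinals) and `store.smi` (one SMILES + identifier per ordinal). Loading
verifies the format version and the decoded length of every posting list;
truncation is an integrity error, never a silently wrong answer. When an
index and a caller disagree on `graphSize`, the manifest wins with a
warning: the index was built at its value and querying at another would be
unsound in one direction and wasteful in the other.

Per-bit document frequencies (the basis of filtering power) come from
posting-list lengths: a bit's occurrence is the fraction of compounds
containing it at least once, not a term frequency.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `graphSize` | 7 bonds | cap on enumerated subgraph size; larger values sharpen screening at the cost of fingerprint size |
| `minCover` | 2 | minimal number of selected bits covering each query atom; 1 screens cheapest, larger values buy back precision on complicated queries |
| `maxBits` | 32 | hard cap on selected bits per query |
| `limit` | unset | optional cap on matcher search states; exceeded ⇒ "undecided" |

The suite checks the two parameter mechanisms at desk scale: with
selection disabled, candidate sets at `graphSize` 7 are subsets of those
at 3 for the same corpus and query; with selection enabled, per-query
false positive rates are non-increasing in `minCover` over
$\{1, 2, 3, 5\}$. Both follow from posting-list containment: the selected
set under a larger `minCover` always contains the selected set under a
smaller one, as long as the `maxBits` cap is not the binding constraint.

## Synthetic data

Everything is tested without external datasets. The generator builds
valence-respecting connected graphs: a random spanning tree over atoms
drawn from {C, N, O, S} (mostly single bonds, occasional doubles where
both partners keep a free valence), an optional extra ring-closing edge,
and with probability 0.3 a complete aromatic 6-ring (occasionally with one
ring nitrogen) — aromatic bonds occur only inside such rings, keeping
notation-driven aromaticity self-consistent. Charges (ammonium-style N⁺)
and isotopes (¹³C) decorate atoms with 2% probability to exercise the
type distinctions. Everything derives from a per-molecule seed, so
corpora are bit-reproducible across platforms. Query sets are random
connected bond subgraphs of corpus members (substructures by
construction, occasionally a single atom), mixed with independently
generated molecules as likely negatives.

Default problem sizes in the test suite — 200-compound corpora, 100-query
soundness sweeps across all parameter settings, 2000 matcher/oracle
pairs, 1000-molecule enumeration and selection sweeps — were chosen as the
smallest scales at which every mechanism (tier bits, ring pathologies,
selection pruning, the `maxBits` cap) is actually exercised.

What the generator does not emulate: realistic functional-group
chemistry, tautomers, stereochemistry, large fused ring systems, or the
size distribution of real registries. Passing tests demonstrate the
engine's combinatorial correctness — soundness, exactness of the matcher,
index integrity — on graphs of comparable size and density to small
organic molecules; they say nothing about screening *efficiency* on any
real database, which depends on real feature-frequency distributions.

## Known limitations

- No aromaticity perception: mixed Kekulé/aromatic corpora will silently
  fail to cross-match; normalize inputs upstream.
- No SMARTS, wildcards, stereochemistry or charge/tautomer normalization;
  queries with `*` are rejected.
- The supported SMILES subset covers the organic subset plus bracket
  atoms; exotic ring-bond-order notations and explicit-H atoms are not
  accepted.
- The index is static: no incremental updates or deletes.
- Embedding counts treat automorphic images as distinct (a benzene ring
  has 12 self-embeddings), which is the convention needed when reasoning
  about backtracking cost.
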