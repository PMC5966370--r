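# Substructural fingerprints: three feature families per molecule
#   1. atom types      - one base feature per distinct (element, charge,
#                        aromatic) tuple, counted with multiplicity
#   2. SSSR rings      - one base feature per distinct smallest-ring shape
#   3. subgraphs       - every connected subgraph of 1..graphSize bonds with
#                        at most one ring, collapsed by canonical tree hash
# Multiplicity is encoded as extra bits, one per power of 2 up to the count
# (tier p reads "feature occurs at least p times"), which preserves the
# substructure-closure property: every bit of a fragment's fingerprint is
# present in the fingerprint of any molecule containing the fragment.
# Isotopes and hydrogen counts never enter feature labels because the matcher
# constrains them only when the query specifies them; labelling with them
# would allow screening to drop true matches.

.KIND_ATOM <- 1L
.KIND_RING <- 2L
.KIND_SUBGRAPH <- 3L

#' Fingerprint parameters
#'
#' @param graphSize maximum number of bonds of an enumerated subgraph
#'   feature (default 7).
#' @return list with class `FingerprintParams`.
#' @export
fingerprintParams <- function(graphSize = 7L) {
  graphSize <- as.integer(graphSize)
  stopifnot(length(graphSize) == 1, graphSize >= 1)
  structure(list(graphSize = graphSize), class = "FingerprintParams")
}

# marshal a Molecule for the C++ kernels (0-based bond endpoints)
.molToC <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  list(elem = .atomicNumber(a$element), chg = a$charge,
       iso = ifelse(is.na(a$isotope), -1L, a$isotope),
       arom = a$aromatic, h = a$hcount, hexp = a$hexplicit,
       bf = b$from - 1L, bt = b$to - 1L, bo = b$order, ba = b$aromatic)
}

#' Multiplicity tiers for a feature count
#'
#' A feature occurring `count` times is indexed under one bit per power of 2
#' not exceeding the count.
#'
#' @param count positive integer occurrence count.
#' @return integer vector of tiers `{1, 2, 4, ...} <= count`.
#' @examples
#' encodeMultiplicity(5)  # 1 2 4
#' @export
encodeMultiplicity <- function(count) {
  count <- as.integer(count)
  stopifnot(length(count) == 1, !is.na(count))
  if (count < 1L) stop("count must be >= 1")
  as.integer(2^(0:floor(log2(count))))
}

#' Atom-type features of a molecule
#'
#' One base feature per distinct (element, charge, aromatic flag) tuple, with
#' its occurrence count; coverage is all atoms of that type.
#'
#' @param mol a [Molecule-class].
#' @return data.frame fragment of a [FeatureSet-class] features table.
#' @export
atomTypeFeatures <- function(mol) {
  n <- natoms(mol)
  if (n == 0L) return(.emptyFeatures())
  a <- mol@atoms
  hash <- cpp_atom_type_hash(.atomicNumber(a$element), a$charge, a$aromatic)
  groups <- split(seq_len(n), hash)
  data.frame(kind = .KIND_ATOM_NAME, hash = as.numeric(names(groups)),
             count = lengths(groups),
             coverage = I(unname(groups)),
             instances = I(rep(list(list()), length(groups))),
             row.names = NULL)
}

.KIND_ATOM_NAME <- "atom_type"
.KIND_RING_NAME <- "ring"
.KIND_SUBGRAPH_NAME <- "subgraph"

.emptyFeatures <- function() {
  data.frame(kind = character(), hash = numeric(), count = integer(),
             coverage = I(list()), instances = I(list()))
}

#' Canonical 36-bit tree hash of a connected subgraph
#'
#' Hashes a connected bond subgraph with at most one ring, invariant under
#' any relabelling of atom indices. Leaves are consecutively removed, each
#' folding its accumulated hash and incident bond label into its neighbour
#' through an order-independent (sorted) combiner; acyclic subgraphs
#' terminate at their 1- or 2-atom centre, 1-ring subgraphs terminate at the
#' ring, which is hashed at its lexically minimal rotation over both
#' traversal directions.
#'
#' @param mol a [Molecule-class].
#' @param subgraph integer vector of bond indices (connected, at most 1 ring).
#' @param kind feature family to mix into the hash ("subgraph" or "ring").
#' @return the 36-bit hash as a double.
#' @export
treeHash <- function(mol, subgraph, kind = "subgraph") {
  cmol <- .molToC(mol)
  kindCode <- switch(kind, subgraph = .KIND_SUBGRAPH, ring = .KIND_RING,
                     stop("unknown kind: ", kind))
  cpp_tree_hash36(natoms(mol), cmol$elem, cmol$chg, cmol$arom,
                  cmol$bf, cmol$bt, cmol$bo, cmol$ba,
                  as.integer(subgraph) - 1L, kindCode)[1]
}

#' SSSR ring features of a molecule
#'
#' One base feature per distinct smallest-ring tree hash, counted with
#' multiplicity over the SSSR; coverage is the union of the atoms of all
#' instances of the shape.
#'
#' @param mol a [Molecule-class].
#' @return data.frame fragment of a [FeatureSet-class] features table.
#' @export
ringFeatures <- function(mol) {
  rings <- sssr(mol)
  if (!length(rings)) return(.emptyFeatures())
  hash <- vapply(rings, function(r) treeHash(mol, r$bonds, "ring"), numeric(1))
  groups <- split(seq_along(rings), hash)
  data.frame(kind = .KIND_RING_NAME, hash = as.numeric(names(groups)),
             count = lengths(groups),
             coverage = I(lapply(groups, function(ix)
               sort(unique(unlist(lapply(rings[ix], `[[`, "atoms")))))),
             instances = I(lapply(groups, function(ix)
               lapply(rings[ix], `[[`, "bonds"))),
             row.names = NULL)
}

#' Enumerate connected bond subgraphs with at most one ring
#'
#' All connected subgraphs of 1..`maxBonds` bonds and cyclomatic number at
#' most 1, each emitted exactly once. Single atoms are not subgraph features
#' (they are covered by atom types).
#'
#' @param mol a [Molecule-class].
#' @param maxBonds maximum bond count per subgraph.
#' @return list of integer bond-index vectors.
#' @examples
#' length(enumerateSubgraphs(parseSmiles("c1ccccc1"), 7))  # 31 for benzene
#' @export
enumerateSubgraphs <- function(mol, maxBonds) {
  maxBonds <- as.integer(maxBonds)
  stopifnot(maxBonds >= 1)
  cmol <- .molToC(mol)
  res <- cpp_subgraph_features(natoms(mol), cmol$elem, cmol$chg, cmol$arom,
                               cmol$bf, cmol$bt, cmol$bo, cmol$ba, maxBonds)
  lapply(res$bonds, function(x) sort(x))
}

.subgraphFeatures <- function(mol, graphSize) {
  cmol <- .molToC(mol)
  res <- cpp_subgraph_features(natoms(mol), cmol$elem, cmol$chg, cmol$arom,
                               cmol$bf, cmol$bt, cmol$bo, cmol$ba,
                               as.integer(graphSize))
  if (!length(res$hash)) return(.emptyFeatures())
  groups <- split(seq_along(res$hash), res$hash)
  b <- mol@bonds
  data.frame(kind = .KIND_SUBGRAPH_NAME, hash = as.numeric(names(groups)),
             count = lengths(groups),
             coverage = I(lapply(groups, function(ix)
               sort(unique(unlist(lapply(res$bonds[ix], function(bb)
                 c(b$from[bb], b$to[bb]))))))),
             instances = I(lapply(groups, function(ix) res$bonds[ix])),
             row.names = NULL)
}

#' Fingerprint a molecule
#'
#' Computes the full substructural fingerprint: atom-type, SSSR-ring and
#' subgraph base features with multiplicity tiers, the bit set, and the
#' bit-to-covered-atoms mapping used by query-side bit selection.
#'
#' @param mol a [Molecule-class].
#' @param params a [fingerprintParams] list.
#' @return a [FeatureSet-class].
#' @examples
#' fp <- fingerprint(parseSmiles("c1ccccc1"))
#' fp
#' @export
fingerprint <- function(mol, params = fingerprintParams()) {
  stopifnot(inherits(params, "FingerprintParams"))
  feats <- rbind(atomTypeFeatures(mol), ringFeatures(mol),
                 .subgraphFeatures(mol, params$graphSize))
  if (!nrow(feats)) {
    return(new("FeatureSet", features = .emptyFeatures(),
               bits = .emptyBits(), atoms = integer(),
               graphSize = params$graphSize))
  }
  tiers <- lapply(feats$count, encodeMultiplicity)
  nt <- lengths(tiers)
  rep_ix <- rep(seq_len(nrow(feats)), nt)
  tier <- unlist(tiers)
  ids <- cpp_feature_id(feats$hash[rep_ix], tier)
  bits <- data.frame(id = ids, kind = feats$kind[rep_ix],
                     hash = feats$hash[rep_ix], tier = as.integer(tier),
                     count = feats$count[rep_ix], row.names = NULL)
  new("FeatureSet", features = feats, bits = bits,
      atoms = seq_len(natoms(mol)), graphSize = params$graphSize)
}

.emptyBits <- function() {
  data.frame(id = numeric(), kind = character(), hash = numeric(),
             tier = integer(), count = integer())
}
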