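#' @useDynLib MolScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Element symbols accepted by the molecular graph model (H through Rn).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

.atomicNumber <- function(symbol) {
  idx <- match(symbol, .ELEMENTS)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Molecule: an attributed undirected molecular graph
#'
#' Atoms carry element symbol, formal charge, isotope (NA when unspecified),
#' an aromatic flag and an attached-hydrogen count; hydrogens are never graph
#' nodes. Bonds carry an order in 1..3 and an aromatic flag. Atom indices are
#' 1-based within R; interfaces that write indices to files use 0-based
#' indices and say so.
#'
#' @slot atoms data.frame with columns element (character), charge (integer),
#'   isotope (integer, NA = unspecified), aromatic (logical), hcount
#'   (integer), hexplicit (logical: hydrogen count was bracket-specified,
#'   which makes it a matching constraint for queries).
#' @slot bonds data.frame with columns from, to (integer, from < to), order
#'   (integer in 1..3), aromatic (logical).
#' @export
setClass("Molecule", representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character()
  need <- c("element", "charge", "isotope", "aromatic", "hcount", "hexplicit")
  if (!all(need %in% names(a))) return("atoms table lacks required columns")
  if (!all(c("from", "to", "order", "aromatic") %in% names(b)))
    return("bonds table lacks required columns")
  if (nrow(a) && !all(a$element %in% .ELEMENTS))
    msg <- c(msg, "invalid element symbol")
  if (nrow(a) && any(a$hcount < 0)) msg <- c(msg, "negative hydrogen count")
  if (nrow(b)) {
    if (any(b$from < 1 | b$to < 1 | b$from > nrow(a) | b$to > nrow(a)))
      msg <- c(msg, "bond endpoint out of range")
    if (any(b$from == b$to)) msg <- c(msg, "bond with identical endpoints")
    if (anyDuplicated(paste(pmin(b$from, b$to), pmax(b$from, b$to))))
      msg <- c(msg, "duplicate bond between one atom pair")
    if (!all(b$order %in% 1:3)) msg <- c(msg, "bond order outside 1..3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Molecule from atom and bond tables
#'
#' @param atoms data.frame of atoms; missing optional columns (charge,
#'   isotope, aromatic, hcount, hexplicit) are filled with defaults.
#' @param bonds data.frame of bonds (columns from, to, plus optional order
#'   and aromatic).
#' @return A [Molecule-class] object.
#' @examples
#' m <- Molecule(data.frame(element = c("C", "O")),
#'               data.frame(from = 1, to = 2))
#' natoms(m)
#' @export
Molecule <- function(atoms = data.frame(element = character()),
                     bonds = data.frame(from = integer(), to = integer())) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- integer(n)
  if (is.null(atoms$isotope)) atoms$isotope <- rep(NA_integer_, n)
  if (is.null(atoms$aromatic)) atoms$aromatic <- logical(n)
  if (is.null(atoms$hcount)) atoms$hcount <- integer(n)
  if (is.null(atoms$hexplicit)) atoms$hexplicit <- logical(n)
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$hcount <- as.integer(atoms$hcount)
  atoms$hexplicit <- as.logical(atoms$hexplicit)
  m <- nrow(bonds)
  if (is.null(bonds$order)) bonds$order <- rep(1L, m)
  if (is.null(bonds$aromatic)) bonds$aromatic <- logical(m)
  fr <- pmin(as.integer(bonds$from), as.integer(bonds$to))
  to <- pmax(as.integer(bonds$from), as.integer(bonds$to))
  bonds <- data.frame(from = fr, to = to,
                      order = as.integer(bonds$order),
                      aromatic = as.logical(bonds$aromatic))
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new("Molecule", atoms = atoms, bonds = bonds)
}

#' @describeIn Molecule number of (non-hydrogen) atoms
#' @param x,object a Molecule
#' @export
natoms <- function(x) nrow(x@atoms)

#' @describeIn Molecule number of bonds
#' @export
nbonds <- function(x) nrow(x@bonds)

#' @describeIn Molecule atom table accessor
#' @export
atoms <- function(x) x@atoms

#' @describeIn Molecule bond table accessor
#' @export
bonds <- function(x) x@bonds

setMethod("show", "Molecule", function(object) {
  comp <- table(object@atoms$element)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat(sprintf("Molecule: %d atoms, %d bonds%s\n", natoms(object),
              nbonds(object),
              if (natoms(object)) paste0(" (", formula, ")") else ""))
  if (natoms(object) > 0 && natoms(object) <= 100)
    cat("  SMILES:", writeSmiles(object), "\n")
})

#' FeatureSet: the substructural fingerprint of one molecule
#'
#' Holds the base features (one per distinct structural hash within each of
#' the three families: atom types, SSSR rings, connected subgraphs), the full
#' bit set including multiplicity tiers, the per-feature coverage map (which
#' atoms caused a feature) and the atom set of the source molecule.
#'
#' @slot features data.frame: kind ("atom_type", "ring" or "subgraph"), hash
#'   (36-bit base hash as double), count (occurrences), plus list columns
#'   coverage (atom indices) and instances (bond-index vectors; empty for
#'   atom types).
#' @slot bits data.frame: id (36-bit FeatureId as double), kind, hash, tier
#'   (power of 2), count (of the base feature).
#' @slot atoms integer vector: all atom indices of the source molecule.
#' @slot graphSize integer: the bond limit the subgraph family was built with.
#' @export
setClass("FeatureSet", representation(features = "data.frame",
                                      bits = "data.frame",
                                      atoms = "integer",
                                      graphSize = "integer"))

setValidity("FeatureSet", function(object) {
  b <- object@bits
  if (nrow(b)) {
    if (any(bitwAnd(b$tier, b$tier - 1L) != 0L))
      return("tiers must be powers of 2")
    if (any(b$tier > b$count)) return("tier exceeds feature count")
    if (any(b$id < 0 | b$id >= 2^36)) return("FeatureId outside 36 bits")
  }
  TRUE
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d base features, %d bits (graphSize = %d)\n",
              nrow(object@features), nrow(object@bits), object@graphSize))
  if (nrow(object@features)) {
    tab <- table(object@features$kind)
    cat("  families:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @describeIn FeatureSet the 36-bit FeatureId values of all bits
#' @param x a FeatureSet
#' @export
featureIds <- function(x) x@bits$id

#' @describeIn FeatureSet the bit table (id, kind, hash, tier, count)
#' @export
featureBits <- function(x) x@bits

#' @describeIn FeatureSet named list mapping each bit id to the atom indices
#'   it covers (the mapping M of the bit-selection algorithm)
#' @export
featureCoverage <- function(x) {
  if (!nrow(x@bits)) return(structure(list(), names = character()))
  key <- paste(x@features$kind, x@features$hash)
  cov <- x@features$coverage
  idx <- match(paste(x@bits$kind, x@bits$hash), key)
  out <- cov[idx]
  names(out) <- as.character(x@bits$id)
  out
}

#' OccurrenceTable: per-bit document frequency over an indexed corpus
#'
#' @slot frequency named numeric: keyword -> number of compounds containing
#'   the bit (document frequency, not term frequency).
#' @slot total integer: corpus size.
#' @export
setClass("OccurrenceTable", representation(frequency = "numeric", total = "integer"))

setMethod("show", "OccurrenceTable", function(object) {
  cat(sprintf("OccurrenceTable: %d distinct bits over %d compounds\n",
              length(object@frequency), object@total))
})

#' InvertedIndex: keyword vocabulary with posting lists and compound store
#'
#' @slot manifest list: formatVersion, graphSize, n (corpus size), ids
#'   (identifier of each ordinal, ordinals are 0-based assignment order),
#'   failures (input records skipped at build time).
#' @slot postings environment: 6-character base64 keyword -> strictly
#'   increasing integer vector of compound ordinals.
#' @slot store list of Molecule, in ordinal order.
#' @export
setClass("InvertedIndex", representation(manifest = "list",
                                         postings = "environment",
                                         store = "list"))

setMethod("show", "InvertedIndex", function(object) {
  cat(sprintf("InvertedIndex: %d compounds, %d keywords (graphSize = %d)\n",
              object@manifest$n, length(ls(object@postings)),
              object@manifest$graphSize))
})

#' @describeIn InvertedIndex build-time parameter manifest
#' @param x an InvertedIndex
#' @export
manifest <- function(x) x@manifest

#' @describeIn InvertedIndex sorted keyword vocabulary
#' @export
vocabulary <- function(x) sort(ls(x@postings))

#' @describeIn InvertedIndex the stored Molecule for one 0-based ordinal
#' @param ordinal 0-based compound ordinal
#' @export
storedMolecule <- function(x, ordinal) x@store[[ordinal + 1L]]

#' SearchResult: screened candidates, verified matches and counts
#'
#' @slot candidates integer: 0-based ordinals that passed screening.
#' @slot verified integer: ordinals confirmed by subgraph matching.
#' @slot undecided integer: ordinals where the matcher hit its state limit.
#' @slot corpusSize integer.
#' @slot plan list: the query plan (selectedBits, discardedSubsumed,
#'   discardedSelected, fullScan flag).
#' @export
setClass("SearchResult", representation(candidates = "integer",
                                        verified = "integer",
                                        undecided = "integer",
                                        corpusSize = "integer",
                                        plan = "list"))

setMethod("show", "SearchResult", function(object) {
  st <- screeningStats(object)
  cat(sprintf(paste0("SearchResult: %d candidates, %d verified, %d undecided",
                     " (corpus %d)\n  precision = %.4g, FPR = %.4g\n"),
              length(object@candidates), length(object@verified),
              length(object@undecided), object@corpusSize,
              st[["precision"]], st[["fpr"]]))
})
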