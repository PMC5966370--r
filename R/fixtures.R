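# Deterministic synthetic molecules: a fixed toy corpus for worked examples
# plus a seeded random generator (valence-respecting spanning tree with
# optional ring closures and aromatic 6-rings) so no external dataset is
# ever needed.

.TOY_SMILES <- c(
  methane      = "C",
  ethane       = "CC",
  propane      = "CCC",
  ethanol      = "CCO",
  benzene      = "c1ccccc1",
  toluene      = "Cc1ccccc1",
  biphenyl     = "c1ccccc1-c1ccccc1",
  naphthalene  = "c1ccc2ccccc2c1",
  pyridine     = "c1ccncc1",
  cycloheptane = "C1CCCCCC1",
  phenol       = "Oc1ccccc1",
  aceticAcid   = "CC(=O)O",
  pyrrole      = "c1cc[nH]c1"
)

#' The built-in toy corpus
#'
#' A fixed set of small named molecules (methane, ethane, propane, ethanol,
#' benzene, toluene, biphenyl, naphthalene, pyridine, cycloheptane, and a
#' few more) used throughout examples and tests.
#'
#' @param smiles return the SMILES strings instead of parsed molecules.
#' @return named list of [Molecule-class] (or named character vector).
#' @export
toyCorpus <- function(smiles = FALSE) {
  if (smiles) return(.TOY_SMILES)
  lapply(.TOY_SMILES, parseSmiles)
}

#' Generator configuration
#'
#' @param seed integer master seed.
#' @param nMolecules number of molecules a corpus should contain.
#' @param atomCountRange integer pair: inclusive atom-count range.
#' @param elements element symbols to draw from.
#' @param ringProbability probability of attempting an extra (non-aromatic)
#'   ring closure, and of embedding an aromatic 6-ring.
#' @return list with class `GeneratorConfig`.
#' @export
generatorConfig <- function(seed = 1L, nMolecules = 100L,
                            atomCountRange = c(4L, 14L),
                            elements = c("C", "N", "O", "S"),
                            ringProbability = 0.3) {
  stopifnot(length(atomCountRange) == 2, atomCountRange[1] >= 1,
            atomCountRange[2] >= atomCountRange[1],
            ringProbability >= 0, ringProbability <= 1,
            all(elements %in% c("C", "N", "O", "S")))
  structure(list(seed = as.integer(seed), nMolecules = as.integer(nMolecules),
                 atomCountRange = as.integer(atomCountRange),
                 elements = elements, ringProbability = ringProbability),
            class = "GeneratorConfig")
}

# run expr under a local RNG state derived from seed, restoring the caller's
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

.MAXVAL <- c(C = 4L, N = 3L, O = 2L, S = 2L)

#' Generate one deterministic random molecule
#'
#' Builds a connected, valence-respecting graph: an optional aromatic
#' 6-ring, a random spanning tree over the remaining atoms (mostly single
#' bonds, occasional double bonds), optional ring-closing edges, and rare
#' (2% per atom) charge or isotope decorations. Deterministic for a given
#' (seed, index) pair.
#'
#' @param config a [generatorConfig].
#' @param index 1-based molecule index within the configured corpus.
#' @return a [Molecule-class].
#' @export
randomMolecule <- function(config = generatorConfig(), index = 1L) {
  localSeed <- (config$seed * 48271 + index * 1009) %% 2147483647
  .withSeed(localSeed, .buildRandomMolecule(config))
}

.buildRandomMolecule <- function(config) {
  n <- sample(seq(config$atomCountRange[1], config$atomCountRange[2]), 1)
  useAromatic <- "C" %in% config$elements && n >= 6 &&
    stats::runif(1) < config$ringProbability
  el <- character(); arom <- logical(); cap <- integer()
  bf <- integer(); bt <- integer(); bo <- integer(); ba <- logical()
  addBond <- function(a, b, order, aromatic) {
    bf[length(bf) + 1L] <<- a; bt[length(bt) + 1L] <<- b
    bo[length(bo) + 1L] <<- order; ba[length(ba) + 1L] <<- aromatic
    used <- if (aromatic) 1L else order
    cap[a] <<- cap[a] - used; cap[b] <<- cap[b] - used
  }
  if (useAromatic) {
    ringEl <- rep("C", 6)
    if ("N" %in% config$elements && stats::runif(1) < 0.3)
      ringEl[sample(6, 1)] <- "N"
    for (i in 1:6) {
      el[i] <- ringEl[i]; arom[i] <- TRUE
      # one valence unit is held by the aromatic system itself
      cap[i] <- .MAXVAL[[ringEl[i]]] - 1L
    }
    for (i in 1:6) addBond(i, if (i < 6) i + 1L else 1L, 1L, TRUE)
  }
  while (length(el) < n) {
    e <- sample(config$elements, 1)
    el <- c(el, e); arom <- c(arom, FALSE); cap <- c(cap, .MAXVAL[[e]])
    a <- length(el)
    if (a > 1L) {
      hosts <- which(cap[-a] >= 1L)
      if (!length(hosts)) { # no free valence anywhere: drop the atom
        el <- el[-a]; arom <- arom[-a]; cap <- cap[-a]
        break
      }
      host <- if (length(hosts) == 1L) hosts else sample(hosts, 1)
      # a double bond may not strand the build: unless this is the last
      # atom, the newcomer must keep a free valence for the next attachment
      order <- if (cap[host] >= 2L && cap[a] >= 2L && !arom[host] &&
                   (cap[a] >= 3L || a == n) &&
                   stats::runif(1) < 0.15) 2L else 1L
      addBond(host, a, order, FALSE)
    }
  }
  # optional extra ring closure between non-adjacent atoms with free valence
  if (length(el) >= 4L && stats::runif(1) < config$ringProbability) {
    free <- which(cap >= 1L)
    if (length(free) >= 2L) {
      pairKey <- paste(pmin(bf, bt), pmax(bf, bt))
      cand <- expand.grid(a = free, b = free)
      cand <- cand[cand$a < cand$b, , drop = FALSE]
      cand <- cand[!(paste(cand$a, cand$b) %in% pairKey), , drop = FALSE]
      if (nrow(cand)) {
        pick <- cand[sample(nrow(cand), 1), ]
        addBond(pick$a, pick$b, 1L, FALSE)
      }
    }
  }
  chg <- integer(length(el)); iso <- rep(NA_integer_, length(el))
  for (a in seq_along(el)) {
    if (el[a] == "N" && !arom[a] && stats::runif(1) < 0.02) {
      chg[a] <- 1L; cap[a] <- cap[a] + 1L  # ammonium-style N+
    }
    if (el[a] == "C" && stats::runif(1) < 0.02) iso[a] <- 13L
  }
  Molecule(data.frame(element = el, charge = chg, isotope = iso,
                      aromatic = arom, hcount = pmax(cap, 0L),
                      hexplicit = FALSE),
           data.frame(from = bf, to = bt, order = bo, aromatic = ba))
}

#' Generate a deterministic corpus
#'
#' @param config a [generatorConfig].
#' @return named list of [Molecule-class] (ids `M0001`, `M0002`, ...).
#' @export
generateCorpus <- function(config = generatorConfig()) {
  mols <- lapply(seq_len(config$nMolecules), function(i)
    randomMolecule(config, i))
  names(mols) <- sprintf("M%04d", seq_len(config$nMolecules))
  mols
}

#' A random connected subquery of a molecule
#'
#' Grows a random connected bond subgraph (or, for bond-free molecules and
#' with small probability, a single atom) and returns it as a standalone
#' molecule. Atom attributes are copied verbatim, so by construction the
#' result is a substructure of `mol`.
#'
#' @param mol a nonempty [Molecule-class].
#' @param seed integer seed.
#' @return a [Molecule-class].
#' @export
randomSubquery <- function(mol, seed = 1L) {
  stopifnot(natoms(mol) >= 1)
  .withSeed((as.integer(seed) * 7919 + 13) %% 2147483647, {
    b <- mol@bonds
    if (nbonds(mol) == 0L || stats::runif(1) < 0.05) {
      a <- sample(natoms(mol), 1)
      .extractSub(mol, atomsKeep = a, bondsKeep = integer())
    } else {
      k <- sample(nbonds(mol), 1)
      inS <- rep(FALSE, nbonds(mol))
      start <- sample(nbonds(mol), 1)
      inS[start] <- TRUE
      atomsIn <- c(b$from[start], b$to[start])
      while (sum(inS) < k) {
        frontier <- which(!inS & (b$from %in% atomsIn | b$to %in% atomsIn))
        if (!length(frontier)) break
        nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1)
        inS[nxt] <- TRUE
        atomsIn <- unique(c(atomsIn, b$from[nxt], b$to[nxt]))
      }
      .extractSub(mol, atomsKeep = sort(atomsIn), bondsKeep = which(inS))
    }
  })
}

.extractSub <- function(mol, atomsKeep, bondsKeep) {
  a <- mol@atoms[atomsKeep, , drop = FALSE]
  a$hexplicit <- FALSE    # a fragment imposes no hydrogen-count constraint
  remap <- integer(natoms(mol)); remap[atomsKeep] <- seq_along(atomsKeep)
  b <- mol@bonds[bondsKeep, , drop = FALSE]
  Molecule(a, data.frame(from = remap[b$from], to = remap[b$to],
                         order = b$order, aromatic = b$aromatic))
}

#' Write molecules to a SMILES file
#'
#' @param mols named list of [Molecule-class].
#' @param path output path (`SMILES<TAB>identifier` per line).
#' @export
writeSmilesFile <- function(mols, path) {
  lines <- vapply(seq_along(mols), function(i)
    paste(writeSmiles(mols[[i]]), names(mols)[i], sep = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
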