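# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check: the embedding oracle
# enumerates injective mappings in plain atom-index order, and the subgraph
# oracle enumerates raw bond subsets.

toy <- toyCorpus()

# exhaustive injective-mapping enumeration: returns the number of complete
# embeddings of query in target under the same compatibility semantics
bruteEmbeddings <- function(query, target, opts = matchOptions()) {
  qa <- atoms(query); ta <- atoms(target)
  qb <- bonds(query); tb <- bonds(target)
  nq <- nrow(qa); nt <- nrow(ta)
  if (nq == 0) return(1L)
  if (nq > nt) return(0L)
  tkey <- paste(pmin(tb$from, tb$to), pmax(tb$from, tb$to))
  bondAt <- function(x, y) which(tkey == paste(min(x, y), max(x, y)))
  count <- 0L
  assign_ <- integer(nq)
  used <- logical(nt)
  recurse <- function(i) {
    if (i > nq) { count <<- count + 1L; return(invisible()) }
    for (t in seq_len(nt)) {
      if (used[t]) next
      if (!atomsCompatible(qa[i, ], ta[t, ], opts)) next
      ok <- TRUE
      for (k in which((qb$from == i & qb$to < i) | (qb$to == i & qb$from < i))) {
        o <- if (qb$from[k] == i) qb$to[k] else qb$from[k]
        j <- bondAt(t, assign_[o])
        if (!length(j) ||
            xor(qb$aromatic[k], tb$aromatic[j]) ||
            (!qb$aromatic[k] && qb$order[k] != tb$order[j])) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_[i] <<- t; used[t] <<- TRUE
      recurse(i + 1L)
      used[t] <<- FALSE
    }
  }
  recurse(1L)
  count
}

# brute-force enumeration of connected bond subsets with <= 1 ring
bruteSubgraphs <- function(mol, maxBonds) {
  b <- bonds(mol)
  nb <- nrow(b)
  out <- list()
  for (size in seq_len(min(maxBonds, nb))) {
    for (ix in utils::combn(nb, size, simplify = FALSE)) {
      atomsIn <- unique(c(b$from[ix], b$to[ix]))
      # connectivity by repeated frontier growth
      seen <- b$from[ix[1]]
      repeat {
        grow <- unique(c(b$to[ix][b$from[ix] %in% seen],
                         b$from[ix][b$to[ix] %in% seen]))
        grow <- setdiff(grow, seen)
        if (!length(grow)) break
        seen <- c(seen, grow)
      }
      if (length(seen) != length(atomsIn)) next
      if (size - length(atomsIn) + 1L > 1L) next
      out[[length(out) + 1L]] <- ix
    }
  }
  out
}

# canonical string for a set of bond subgraphs, for exact set comparison
subgraphKey <- function(sets) sort(vapply(sets, function(x)
  paste(sort(x), collapse = ","), character(1)))

# apply a random atom permutation to a molecule, returning the permuted
# molecule and the bond-index mapping old -> new
permuteAtoms <- function(mol, perm) {
  a <- atoms(mol)[order(perm), , drop = FALSE]
  b <- bonds(mol)
  Molecule(a, data.frame(from = perm[b$from], to = perm[b$to],
                         order = b$order, aromatic = b$aromatic))
}

# graph isomorphism check via two-way substructure matching
isIsomorphic <- function(m1, m2) {
  natoms(m1) == natoms(m2) && nbonds(m1) == nbonds(m2) &&
    isTRUE(isSubstructure(m1, m2)) && isTRUE(isSubstructure(m2, m1))
}
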