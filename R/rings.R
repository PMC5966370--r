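# Ring perception: a deterministic Smallest Set of Smallest Rings, computed
# as a minimum cycle basis. Candidate cycles come from the Horton set
# (shortest-path trees rooted at every vertex, one candidate per root/edge
# pair) plus the fundamental cycles of a spanning forest as a completeness
# fallback; candidates are taken in order of (length, lexicographically
# smallest sorted bond-index set) and kept when GF(2)-independent of the
# rings already chosen, until exactly bonds - atoms + components rings are
# selected.

.adjList <- function(mol) {
  n <- natoms(mol)
  adj <- rep(list(integer()), n)
  bnd <- rep(list(integer()), n)
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$from[k]]] <- c(adj[[b$from[k]]], b$to[k])
    bnd[[b$from[k]]] <- c(bnd[[b$from[k]]], k)
    adj[[b$to[k]]] <- c(adj[[b$to[k]]], b$from[k])
    bnd[[b$to[k]]] <- c(bnd[[b$to[k]]], k)
  }
  list(adj = adj, bnd = bnd)
}

.nComponents <- function(mol) {
  n <- natoms(mol)
  if (n == 0L) return(0L)
  adj <- .adjList(mol)$adj
  seen <- logical(n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stk <- s; seen[s] <- TRUE
    while (length(stk)) {
      a <- stk[length(stk)]; stk <- stk[-length(stk)]
      nxt <- adj[[a]][!seen[adj[[a]]]]
      seen[nxt] <- TRUE
      stk <- c(stk, nxt)
    }
  }
  comp
}

#' Cyclomatic number of a molecule
#'
#' bonds - atoms + connected components: the size of any cycle basis, and the
#' number of rings [sssr] returns.
#'
#' @param mol a [Molecule-class].
#' @export
cyclomaticNumber <- function(mol) nbonds(mol) - natoms(mol) + .nComponents(mol)

# BFS with deterministic parent choice (neighbours scanned in index order)
.bfs <- function(adj, bnd, root, n) {
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  parentBond <- rep(NA_integer_, n)
  dist[root] <- 0L
  queue <- root; qi <- 1L
  while (qi <= length(queue)) {
    a <- queue[qi]; qi <- qi + 1L
    ord <- order(adj[[a]])
    for (j in ord) {
      nb <- adj[[a]][j]
      if (is.na(dist[nb])) {
        dist[nb] <- dist[a] + 1L
        parent[nb] <- a; parentBond[nb] <- bnd[[a]][j]
        queue <- c(queue, nb)
      }
    }
  }
  list(dist = dist, parent = parent, parentBond = parentBond)
}

.pathTo <- function(bfs, v) {
  atoms <- integer(); bondsOnPath <- integer()
  while (!is.na(bfs$parent[v])) {
    atoms <- c(atoms, v); bondsOnPath <- c(bondsOnPath, bfs$parentBond[v])
    v <- bfs$parent[v]
  }
  list(atoms = c(atoms, v), bonds = bondsOnPath)  # v .. root
}

#' Smallest Set of Smallest Rings
#'
#' Returns exactly `bonds - atoms + components` rings; each ring is a
#' shortest cycle that is GF(2)-independent of the rings selected before it.
#' Ties between equal-length candidates are broken by the lexicographically
#' smallest sorted bond-index set, so the output is deterministic for a fixed
#' atom ordering.
#'
#' @param mol a [Molecule-class].
#' @return list of rings, each a list with `atoms` (ordered atom cycle) and
#'   `bonds` (the corresponding ordered bond indices).
#' @examples
#' length(sssr(parseSmiles("c1ccc2ccccc2c1")))  # naphthalene: 2
#' @export
sssr <- function(mol) {
  target <- cyclomaticNumber(mol)
  if (target <= 0L) return(list())
  n <- natoms(mol); nb <- nbonds(mol)
  al <- .adjList(mol)
  b <- mol@bonds

  candKeys <- character(); candBonds <- list()
  addCand <- function(bondIdx) {
    key <- paste(sort(bondIdx), collapse = ",")
    if (!key %in% candKeys) {
      candKeys[length(candKeys) + 1L] <<- key
      candBonds[[length(candBonds) + 1L]] <<- bondIdx
    }
  }

  for (v in seq_len(n)) {
    bfs <- .bfs(al$adj, al$bnd, v, n)
    for (k in seq_len(nb)) {
      x <- b$from[k]; y <- b$to[k]
      if (is.na(bfs$dist[x]) || is.na(bfs$dist[y])) next
      if (bfs$parentBond[x] %in% k || bfs$parentBond[y] %in% k) next  # tree edge
      px <- .pathTo(bfs, x); py <- .pathTo(bfs, y)
      shared <- intersect(px$atoms, py$atoms)
      if (length(shared) != 1L) next          # paths must meet only at v
      cyc <- c(px$bonds, k, py$bonds)
      if (anyDuplicated(cyc)) next
      addCand(cyc)
    }
  }
  # fundamental cycles of the BFS forest guarantee a complete basis
  bfsAll <- list(); roots <- integer()
  seen <- logical(n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    bf <- .bfs(al$adj, al$bnd, s, n)
    seen[!is.na(bf$dist)] <- TRUE
    for (k in seq_len(nb)) {
      x <- b$from[k]; y <- b$to[k]
      if (is.na(bf$dist[x]) || k %in% c(bf$parentBond[x], bf$parentBond[y])) next
      px <- .pathTo(bf, x); py <- .pathTo(bf, y)
      common <- intersect(px$bonds, py$bonds)
      cyc <- c(setdiff(px$bonds, common), k, setdiff(py$bonds, common))
      addCand(cyc)
    }
  }

  len <- lengths(candBonds)
  keySorted <- vapply(candBonds, function(x) paste(sprintf("%06d", sort(x)), collapse = ","),
                      character(1))
  ordCand <- order(len, keySorted)

  # greedy GF(2) selection
  basis <- matrix(logical(0), nrow = 0, ncol = nb)
  pivots <- integer()
  chosen <- list()
  for (ci in ordCand) {
    vec <- logical(nb); vec[candBonds[[ci]]] <- TRUE
    red <- vec
    for (r in seq_len(nrow(basis))) {
      if (red[pivots[r]]) red <- xor(red, basis[r, ])
    }
    if (!any(red)) next
    basis <- rbind(basis, red)
    pivots <- c(pivots, which(red)[1])
    chosen[[length(chosen) + 1L]] <- candBonds[[ci]]
    if (length(chosen) == target) break
  }
  stopifnot(length(chosen) == target)

  lapply(chosen, function(bondIdx) .orderRing(mol, bondIdx))
}

# order an (unordered) bond set known to be a simple cycle into an atom/bond walk
.orderRing <- function(mol, bondIdx) {
  b <- mol@bonds[bondIdx, ]
  ends <- cbind(b$from, b$to)
  start <- min(ends)
  atomsOrd <- start
  bondsOrd <- integer()
  cur <- start; prevBond <- 0L
  repeat {
    j <- which((ends[, 1] == cur | ends[, 2] == cur) & seq_along(bondIdx) != prevBond)[1]
    nxt <- if (ends[j, 1] == cur) ends[j, 2] else ends[j, 1]
    bondsOrd <- c(bondsOrd, bondIdx[j])
    prevBond <- j
    if (nxt == start) break
    atomsOrd <- c(atomsOrd, nxt)
    cur <- nxt
  }
  list(atoms = atomsOrd, bonds = bondsOrd)
}

#' Cyclomatic number of a connected bond subgraph
#'
#' @param mol a [Molecule-class].
#' @param subgraph integer vector of bond indices forming a connected
#'   subgraph of `mol`.
#' @return `#bonds - #atoms + 1` of the subgraph.
#' @export
ringBondCount <- function(mol, subgraph) {
  subgraph <- as.integer(subgraph)
  stopifnot(length(subgraph) >= 1, all(subgraph >= 1), all(subgraph <= nbonds(mol)))
  b <- mol@bonds[subgraph, ]
  atomsIn <- unique(c(b$from, b$to))
  # connectivity check over the subgraph
  seen <- b$from[1]
  repeat {
    grow <- unique(c(b$to[b$from %in% seen], b$from[b$to %in% seen]))
    grow <- setdiff(grow, seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  if (length(seen) != length(atomsIn))
    stop("subgraph bonds do not form a connected subgraph")
  length(subgraph) - length(atomsIn) + 1L
}
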