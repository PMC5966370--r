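# SMILES reading and writing for the supported subset: organic-subset atoms,
# bracket atoms with isotope / charge / explicit hydrogens, bond symbols
# - = # :, lowercase aromatic atoms, ring closures (digit and %nn), branches
# and dot-separated fragments. Stereo markers are accepted and discarded.
# Aromaticity is taken from the notation only; no perception is performed, so
# Kekule-written and aromatic-written benzene are distinct inputs.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

.VALENCES <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
                  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L)

.parseError <- function(pos, msg) {
  stop(structure(class = c("smilesParseError", "error", "condition"),
                 list(message = sprintf("SMILES parse error at position %d: %s",
                                        pos, msg),
                      call = NULL, position = pos)))
}

# implicit hydrogens from standard valences; `used` counts bond orders with
# aromatic bonds as 1, plus 1 extra for an aromatic atom
.implicitH <- function(element, used) {
  vals <- .VALENCES[[element]]
  if (is.null(vals)) return(0L)
  ok <- vals[vals >= used]
  if (!length(ok)) return(0L)
  as.integer(ok[1] - used)
}

#' Parse a SMILES string into a Molecule
#'
#' Supports the organic subset, bracket atoms (isotope, charge, explicit H),
#' bond symbols `-`, `=`, `#`, `:` (plus `/` and `\` read as plain single
#' bonds), lowercase aromatic atoms, ring-closure digits and `%nn`, branches
#' and dot-separated fragments. Aromatic flags come from the notation alone;
#' no aromaticity perception is done. Wildcard atoms (`*`) and explicit
#' hydrogen atoms (`[H]`) are rejected. Implicit hydrogen counts are filled
#' from standard valence rules; for aromatic atoms one valence unit is
#' reserved for the ring system.
#'
#' @param text a single SMILES string.
#' @return A [Molecule-class].
#' @examples
#' parseSmiles("c1ccccc1")    # benzene
#' parseSmiles("[13CH4]")     # isotope-labelled methane
#' @export
parseSmiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  nc <- length(chars)
  if (nc == 0) .parseError(1, "empty SMILES")

  el <- character(); chg <- integer(); iso <- integer()
  arom <- logical(); hct <- integer(); hexp <- logical()
  bFrom <- integer(); bTo <- integer(); bSym <- character()
  nAtom <- 0L

  prev <- NA_integer_
  pending <- ""            # bond symbol awaiting its second atom
  pendingPos <- 0L
  stack <- integer()
  rings <- list()          # "digit" -> list(atom, sym, pos)

  addAtom <- function(element, aromatic, charge = 0L, isotope = NA_integer_,
                      h = NA_integer_, hexplicit = FALSE) {
    nAtom <<- nAtom + 1L
    el[nAtom] <<- element; chg[nAtom] <<- charge; iso[nAtom] <<- isotope
    arom[nAtom] <<- aromatic; hct[nAtom] <<- h; hexp[nAtom] <<- hexplicit
    if (!is.na(prev)) {
      bFrom[length(bFrom) + 1L] <<- prev
      bTo[length(bTo) + 1L] <<- nAtom
      bSym[length(bSym) + 1L] <<- pending
    } else if (nzchar(pending)) {
      .parseError(pendingPos, "bond symbol with no preceding atom")
    }
    pending <<- ""
    prev <<- nAtom
  }

  closeRing <- function(digit, pos) {
    if (is.na(prev)) .parseError(pos, "ring closure with no preceding atom")
    key <- as.character(digit)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, sym = pending, pos = pos)
    } else {
      open <- rings[[key]]
      sym <- pending
      if (nzchar(open$sym) && nzchar(sym) && open$sym != sym)
        .parseError(pos, sprintf("conflicting bond symbols for ring closure %s", key))
      if (!nzchar(sym)) sym <- open$sym
      if (open$atom == prev)
        .parseError(pos, "ring closure bonds an atom to itself")
      bFrom[length(bFrom) + 1L] <<- open$atom
      bTo[length(bTo) + 1L] <<- prev
      bSym[length(bSym) + 1L] <<- sym
      rings[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= nc) {
    ch <- chars[i]
    two <- if (i < nc) paste0(ch, chars[i + 1L]) else ""
    if (ch == "*") .parseError(i, "wildcard atoms are not supported")
    if (two %in% c("Cl", "Br")) {
      addAtom(two, FALSE); i <- i + 2L
    } else if (ch %in% .ORGANIC) {
      addAtom(ch, FALSE); i <- i + 1L
    } else if (ch %in% .AROMATIC_ORGANIC) {
      addAtom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      isoNum <- NA_integer_
      digs <- ""
      while (j <= nc && grepl("[0-9]", chars[j])) { digs <- paste0(digs, chars[j]); j <- j + 1L }
      if (nzchar(digs)) isoNum <- as.integer(digs)
      if (j > nc) .parseError(i, "unterminated bracket atom")
      if (chars[j] == "*") .parseError(j, "wildcard atoms are not supported")
      aromFlag <- FALSE; element <- NULL
      twoB <- if (j < nc) paste0(chars[j], chars[j + 1L]) else ""
      if (twoB %in% c("se", "as")) {
        element <- c(se = "Se", as = "As")[[twoB]]; aromFlag <- TRUE; j <- j + 2L
      } else if (chars[j] %in% .AROMATIC_ORGANIC) {
        element <- toupper(chars[j]); aromFlag <- TRUE; j <- j + 1L
      } else if (grepl("[A-Z]", chars[j])) {
        element <- chars[j]; j <- j + 1L
        if (j <= nc && grepl("[a-z]", chars[j]) &&
            paste0(element, chars[j]) %in% .ELEMENTS) {
          element <- paste0(element, chars[j]); j <- j + 1L
        }
      } else .parseError(j, sprintf("unexpected character '%s' in bracket atom", chars[j]))
      if (element == "H")
        .parseError(i, "explicit hydrogen atoms are not supported (hydrogens live in hcount)")
      if (!element %in% .ELEMENTS)
        .parseError(i, sprintf("unknown element '%s'", element))
      while (j <= nc && chars[j] == "@") j <- j + 1L  # chirality: discard
      hNum <- 0L
      if (j <= nc && chars[j] == "H") {
        j <- j + 1L; digs <- ""
        while (j <= nc && grepl("[0-9]", chars[j])) { digs <- paste0(digs, chars[j]); j <- j + 1L }
        hNum <- if (nzchar(digs)) as.integer(digs) else 1L
      }
      charge <- 0L
      if (j <= nc && chars[j] %in% c("+", "-")) {
        sign <- if (chars[j] == "+") 1L else -1L
        j <- j + 1L; count <- 1L; digs <- ""
        while (j <= nc && grepl("[0-9]", chars[j])) { digs <- paste0(digs, chars[j]); j <- j + 1L }
        if (nzchar(digs)) count <- as.integer(digs)
        else while (j <= nc && chars[j] == c("+", "-")[(3 - sign) / 2]) { count <- count + 1L; j <- j + 1L }
        charge <- sign * count
      }
      if (j <= nc && chars[j] == ":") {  # atom-class annotation: discard
        j <- j + 1L
        while (j <= nc && grepl("[0-9]", chars[j])) j <- j + 1L
      }
      if (j > nc || chars[j] != "]") .parseError(i, "unterminated bracket atom")
      addAtom(element, aromFlag, charge, isoNum, hNum, TRUE)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (nzchar(pending)) .parseError(i, "two consecutive bond symbols")
      pending <- ch; pendingPos <- i; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      if (nzchar(pending)) .parseError(i, "two consecutive bond symbols")
      pending <- "-"; pendingPos <- i; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) .parseError(i, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .parseError(i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending)) .parseError(i, "bond symbol before '.'")
      prev <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nc || !grepl("[0-9]", chars[i + 1L]) || !grepl("[0-9]", chars[i + 2L]))
        .parseError(i, "'%' must be followed by two digits")
      closeRing(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else {
      .parseError(i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack)) .parseError(nc, "unclosed branch '('")
  if (length(rings))
    .parseError(nc, sprintf("unmatched ring closure(s): %s",
                            paste(names(rings), collapse = ", ")))
  if (nAtom == 0L) .parseError(1, "no atoms")

  # resolve bond orders and aromatic flags
  m <- length(bFrom)
  bOrder <- integer(m); bArom <- logical(m)
  for (k in seq_len(m)) {
    sym <- bSym[k]
    if (sym == "") {
      if (arom[bFrom[k]] && arom[bTo[k]]) { bOrder[k] <- 1L; bArom[k] <- TRUE }
      else bOrder[k] <- 1L
    } else if (sym == "-") bOrder[k] <- 1L
    else if (sym == "=") bOrder[k] <- 2L
    else if (sym == "#") bOrder[k] <- 3L
    else if (sym == ":") { bOrder[k] <- 1L; bArom[k] <- TRUE }
  }
  dupKey <- paste(pmin(bFrom, bTo), pmax(bFrom, bTo))
  if (anyDuplicated(dupKey)) .parseError(nc, "duplicate bond between one atom pair")

  # implicit hydrogens for organic-subset atoms written without brackets
  for (a in seq_len(nAtom)) {
    if (!is.na(hct[a])) next
    inc <- which(bFrom == a | bTo == a)
    used <- sum(ifelse(bArom[inc], 1L, bOrder[inc])) + as.integer(arom[a])
    hct[a] <- .implicitH(el[a], used)
  }

  Molecule(data.frame(element = el, charge = chg, isotope = iso,
                      aromatic = arom, hcount = hct, hexplicit = hexp),
           data.frame(from = bFrom, to = bTo, order = bOrder, aromatic = bArom))
}

# bond symbol as it must appear between two given atoms
.bondSymbol <- function(order, aromatic, arom1, arom2) {
  if (aromatic) { if (arom1 && arom2) "" else ":" }
  else if (order == 1L) { if (arom1 && arom2) "-" else "" }
  else if (order == 2L) "="
  else "#"
}

.atomToken <- function(mol, a, usedValence) {
  at <- mol@atoms[a, ]
  lower <- tolower(at$element)
  plainOk <- at$element %in% .ORGANIC &&
    (!at$aromatic || lower %in% .AROMATIC_ORGANIC) &&
    at$charge == 0L && is.na(at$isotope) &&
    .implicitH(at$element, usedValence) == at$hcount
  if (plainOk) {
    if (at$aromatic) lower else at$element
  } else {
    sym <- if (at$aromatic && lower %in% c(.AROMATIC_ORGANIC, "se", "as"))
      lower else at$element
    paste0("[",
           if (!is.na(at$isotope)) at$isotope else "",
           sym,
           if (at$hcount == 1L) "H" else if (at$hcount > 1L) paste0("H", at$hcount) else "",
           if (at$charge > 0L) paste0("+", if (at$charge > 1L) at$charge else ""),
           if (at$charge < 0L) paste0("-", if (at$charge < -1L) -at$charge else ""),
           "]")
  }
}

#' Serialize a Molecule to SMILES
#'
#' Bracket notation is emitted only where needed (charge, isotope,
#' bracket-specified hydrogens, or hydrogen counts that valence rules would
#' not reproduce). Reparsing the output yields an isomorphic molecular graph.
#'
#' @param mol a [Molecule-class].
#' @return a SMILES string.
#' @export
writeSmiles <- function(mol) {
  n <- natoms(mol)
  if (n == 0L) return("")
  b <- mol@bonds
  adj <- rep(list(integer()), n)     # incident bond indices, ordered
  for (k in seq_len(nrow(b))) {
    adj[[b$from[k]]] <- c(adj[[b$from[k]]], k)
    adj[[b$to[k]]] <- c(adj[[b$to[k]]], k)
  }
  other <- function(k, a) if (b$from[k] == a) b$to[k] else b$from[k]

  visited <- logical(n); usedBond <- logical(nrow(b))
  children <- rep(list(integer()), n)  # tree bond indices, in DFS order
  ringAt <- rep(list(integer()), n)    # ring-closure numbers at each atom
  ringBondOf <- integer()              # number -> bond index
  nRing <- 0L
  roots <- integer()

  dfs <- function(a) {
    visited[a] <<- TRUE
    for (k in adj[[a]]) {
      if (usedBond[k]) next
      nb <- other(k, a)
      if (!visited[nb]) {
        usedBond[k] <<- TRUE
        children[[a]] <<- c(children[[a]], k)
        dfs(nb)
      } else {
        usedBond[k] <<- TRUE
        nRing <<- nRing + 1L
        if (nRing > 99L) stop("too many ring closures for SMILES output")
        ringBondOf[nRing] <<- k
        ringAt[[a]] <<- c(ringAt[[a]], nRing)
        ringAt[[nb]] <<- c(ringAt[[nb]], nRing)
      }
    }
  }
  for (s in seq_len(n)) {
    if (visited[s]) next
    roots <- c(roots, s)
    dfs(s)
  }

  arom <- mol@atoms$aromatic
  usedVal <- vapply(seq_len(n), function(a) {
    inc <- adj[[a]]
    sum(ifelse(b$aromatic[inc], 1L, b$order[inc])) + as.integer(arom[a])
  }, integer(1))

  ringEmitted <- logical(nRing)
  emit <- function(a) {
    out <- .atomToken(mol, a, usedVal[a])
    for (num in ringAt[[a]]) {
      k <- ringBondOf[num]
      sym <- if (ringEmitted[num]) "" else
        .bondSymbol(b$order[k], b$aromatic[k], arom[b$from[k]], arom[b$to[k]])
      ringEmitted[num] <<- TRUE
      out <- paste0(out, sym, if (num > 9L) paste0("%", num) else num)
    }
    kids <- children[[a]]
    if (length(kids)) {
      parts <- vapply(kids, function(k) {
        nb <- other(k, a)
        paste0(.bondSymbol(b$order[k], b$aromatic[k], arom[a], arom[nb]), emit(nb))
      }, character(1))
      if (length(parts) > 1L)
        out <- paste0(out, paste0("(", parts[-length(parts)], ")", collapse = ""))
      out <- paste0(out, parts[length(parts)])
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

#' Read a SMILES file
#'
#' Each nonempty line is `SMILES` or `SMILES<TAB>identifier`; lines starting
#' with `#` are comments. Lines that fail to parse are reported and skipped,
#' and counted in the returned `failures`.
#'
#' @param path path to a `.smi` file (UTF-8).
#' @param quiet suppress per-line failure messages.
#' @return list with `molecules` (named list of [Molecule-class], names are
#'   identifiers; missing identifiers become `L<line>`), `failures` (count)
#'   and `errors` (messages for the skipped lines).
#' @export
readSmilesFile <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  mols <- list(); errs <- character()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- if (length(fields) >= 2 && nzchar(fields[2])) fields[2] else paste0("L", ln)
    res <- tryCatch(parseSmiles(fields[1]), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("line %d (%s): %s", ln, id, conditionMessage(res))
      errs <- c(errs, msg)
      if (!quiet) message("skipping ", msg)
    } else {
      mols[[id]] <- res
    }
  }
  list(molecules = mols, failures = length(errs), errors = errs)
}
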