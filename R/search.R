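# Query-side fingerprint reduction and search. Reduction has two steps:
# subsumption discard (provably adds no false positives) and statistical bit
# selection driven by per-bit filtering power, followed by posting-list
# screening and VF2 verification.

#' Bit-selection parameters
#'
#' @param minCover minimal number of selected bits that must cover each
#'   query atom (default 2).
#' @param maxBits hard cap on the number of selected bits (default 32).
#' @param selectEnabled run the statistical selection step (default TRUE);
#'   when FALSE the full subsumption-reduced fingerprint is used.
#' @return list with class `SelectionParams`.
#' @export
selectionParams <- function(minCover = 2L, maxBits = 32L, selectEnabled = TRUE) {
  minCover <- as.integer(minCover); maxBits <- as.integer(maxBits)
  stopifnot(minCover >= 1, maxBits >= 1)
  structure(list(minCover = minCover, maxBits = maxBits,
                 selectEnabled = isTRUE(selectEnabled)),
            class = "SelectionParams")
}

#' Subsumption reduction of a query fingerprint
#'
#' Discards query bits that could cost true matches or whose presence in a
#' target is implied by other retained bits, so screening with the reduced
#' set can never lose a true match: (0) ring-kind bits are dropped outright,
#' because the smallest-ring set is not monotone under graph extension - an
#' SSSR ring of the query need not be an SSSR ring of a molecule containing
#' the query, so ring bits are the one family that could produce screening
#' false negatives (ring shapes up to graphSize bonds are still screened,
#' through their subgraph-kind bits); (a) within each base feature only the
#' highest multiplicity tier is kept (its posting list is a subset of the
#' lower tiers'); (b) a subgraph shape's remaining tier-p bit is dropped
#' when a single instance of another subgraph feature contains at least p
#' distinct instances of the shape (a target holding the larger instance
#' necessarily holds p copies of the smaller shape - for p = 1 this is plain
#' bond-set containment); (c) a single-occurrence atom-type bit is dropped
#' when its atom is covered by a retained subgraph feature (whose hash
#' embeds that atom's label).
#'
#' @param fs a query [FeatureSet-class].
#' @return a [FeatureSet-class] with the reduced bit set (features and
#'   coverage unchanged).
#' @export
subsumptionReduce <- function(fs) {
  bits <- fs@bits
  if (!nrow(bits)) return(fs)
  # (0) ring-kind bits never screen: SSSR is not subgraph-monotone
  bits <- bits[bits$kind != .KIND_RING_NAME, , drop = FALSE]
  if (!nrow(bits)) {
    rownames(bits) <- NULL
    return(new("FeatureSet", features = fs@features, bits = bits,
               atoms = fs@atoms, graphSize = fs@graphSize))
  }
  # (a) top tier per base feature
  key <- paste(bits$kind, bits$hash)
  top <- unlist(lapply(split(seq_len(nrow(bits)), key), function(ix)
    ix[which.max(bits$tier[ix])]), use.names = FALSE)
  bits <- bits[sort(top), , drop = FALSE]

  feats <- fs@features
  fkey <- paste(feats$kind, feats$hash)

  # (b) a subgraph shape S whose top tier is p is implied whenever a single
  # instance of some other subgraph feature contains >= p distinct instances
  # of S: any target holding that instance then holds >= p copies of S.
  # Mutual dropping is impossible (containment forces strictly larger
  # instances), so checking against all other features is chain-safe.
  sg <- feats[feats$kind == .KIND_SUBGRAPH_NAME, , drop = FALSE]
  dropHash <- numeric()
  if (nrow(sg) > 1) {
    allInst <- sg$instances
    topTier <- vapply(sg$count, function(cc) max(encodeMultiplicity(cc)),
                      integer(1))
    for (i in seq_len(nrow(sg))) {
      own <- allInst[[i]]
      p <- topTier[i]
      implied <- FALSE
      for (j in seq_len(nrow(sg))) {
        if (j == i) next
        for (inst in allInst[[j]]) {
          if (length(inst) <= length(own[[1]])) next
          inside <- sum(vapply(own, function(o) all(o %in% inst), logical(1)))
          if (inside >= p) { implied <- TRUE; break }
        }
        if (implied) break
      }
      if (implied) dropHash <- c(dropHash, sg$hash[i])
    }
    if (length(dropHash))
      bits <- bits[!(bits$kind == .KIND_SUBGRAPH_NAME &
                     bits$hash %in% dropHash), , drop = FALSE]
  }

  # (c) single-occurrence atom-type bits covered by a retained subgraph
  retained <- feats$kind == .KIND_SUBGRAPH_NAME & !(feats$hash %in% dropHash)
  coveredAtoms <- sort(unique(unlist(feats$coverage[retained])))
  if (length(coveredAtoms)) {
    at <- feats$kind == .KIND_ATOM_NAME & feats$count == 1L
    dropAtom <- feats$hash[at][vapply(feats$coverage[at], function(cov)
      all(cov %in% coveredAtoms), logical(1))]
    if (length(dropAtom))
      bits <- bits[!(bits$kind == .KIND_ATOM_NAME &
                     bits$hash %in% dropAtom), , drop = FALSE]
  }
  rownames(bits) <- NULL
  new("FeatureSet", features = feats, bits = bits, atoms = fs@atoms,
      graphSize = fs@graphSize)
}

#' Statistical bit selection (filtering-power driven)
#'
#' Implements the covering-counter selection: every query atom gets a
#' counter starting at zero; bits are visited in descending filtering power
#' (ascending corpus occurrence, ties broken by ascending FeatureId); a bit
#' is kept iff some atom it covers still has a counter below `minCover`,
#' whereupon the counters of all its covered atoms are incremented; at most
#' `maxBits` bits are kept. Bits never seen in the corpus sort first - an
#' empty posting list has maximal filtering power.
#'
#' @param fs a subsumption-reduced query [FeatureSet-class].
#' @param table the corpus [OccurrenceTable-class].
#' @param params [selectionParams].
#' @return the query plan: list with `selectedBits` (FeatureId vector, in
#'   selection order), `discardedSelected`, and `occ` (occurrence of each
#'   selected bit).
#' @export
selectBits <- function(fs, table, params = selectionParams()) {
  bits <- fs@bits
  if (!nrow(bits))
    return(list(selectedBits = numeric(), discardedSelected = 0L, occ = numeric()))
  occ <- occurrence(table, bits$id)
  ord <- order(occ, bits$id)
  cov <- featureCoverage(fs)
  counters <- integer(length(fs@atoms))
  names(counters) <- as.character(fs@atoms)
  sel <- numeric(); selOcc <- numeric()
  for (i in ord) {
    if (length(sel) >= params$maxBits) break
    atomsCovered <- cov[[as.character(bits$id[i])]]
    if (any(counters[as.character(atomsCovered)] < params$minCover)) {
      counters[as.character(atomsCovered)] <-
        counters[as.character(atomsCovered)] + 1L
      sel <- c(sel, bits$id[i]); selOcc <- c(selOcc, occ[i])
    }
  }
  list(selectedBits = sel,
       discardedSelected = nrow(bits) - length(sel),
       occ = selOcc)
}

#' Plan a query: subsumption reduction plus optional bit selection
#'
#' @param fs the raw query [FeatureSet-class].
#' @param table the corpus [OccurrenceTable-class].
#' @param params [selectionParams].
#' @return list: `selectedBits`, `discardedSubsumed`, `discardedSelected`.
#' @export
queryPlan <- function(fs, table, params = selectionParams()) {
  reduced <- subsumptionReduce(fs)
  nSub <- nrow(fs@bits) - nrow(reduced@bits)
  if (params$selectEnabled) {
    sel <- selectBits(reduced, table, params)
    list(selectedBits = sel$selectedBits, discardedSubsumed = nSub,
         discardedSelected = sel$discardedSelected)
  } else {
    list(selectedBits = reduced@bits$id, discardedSubsumed = nSub,
         discardedSelected = 0L)
  }
}

#' Substructure search against an index
#'
#' Fingerprints the query with the index's own graphSize, reduces and
#' (optionally) selects bits, screens via posting-list intersection, and
#' verifies every candidate with the VF2 matcher. A query whose reduced
#' fingerprint is empty falls back to full-scan verification with a warning.
#'
#' @param index an [InvertedIndex-class].
#' @param query a [Molecule-class].
#' @param sel [selectionParams].
#' @param opts [matchOptions]; matcher-undecided compounds are reported in
#'   the `undecided` slot, never silently dropped.
#' @param params optional [fingerprintParams]; when its graphSize differs
#'   from the index manifest a warning is issued and the manifest wins.
#' @return a [SearchResult-class].
#' @examples
#' idx <- buildIndex(toyCorpus())
#' searchSubstructure(idx, parseSmiles("c1ccccc1"))
#' @export
searchSubstructure <- function(index, query, sel = selectionParams(),
                               opts = matchOptions(), params = NULL) {
  gs <- index@manifest$graphSize
  if (!is.null(params) && params$graphSize != gs) {
    warning("query graphSize ", params$graphSize,
            " overridden by index manifest value ", gs)
  }
  fs <- fingerprint(query, fingerprintParams(gs))
  plan <- queryPlan(fs, .occurrenceFor(index, featureIds(fs)), sel)
  if (!length(plan$selectedBits)) {
    warning("query produced no screening bits; falling back to full scan")
    cand <- if (index@manifest$n > 0) 0:(index@manifest$n - 1L) else integer()
    plan$fullScan <- TRUE
  } else {
    cand <- candidates(index, plan$selectedBits)
    plan$fullScan <- FALSE
  }
  verified <- integer(); undecided <- integer()
  for (ord in cand) {
    ok <- isSubstructure(query, index@store[[ord + 1L]], opts)
    if (is.na(ok)) undecided <- c(undecided, ord)
    else if (ok) verified <- c(verified, ord)
  }
  new("SearchResult", candidates = as.integer(sort(cand)),
      verified = as.integer(sort(verified)),
      undecided = as.integer(sort(undecided)),
      corpusSize = as.integer(index@manifest$n), plan = plan)
}

#' Screening-efficiency statistics of a search result
#'
#' Precision is the ratio of true positives to all screened positives (1
#' when nothing was screened in: no decision was wrong); the false positive
#' rate is the ratio of false screened positives to all true negatives (0
#' when there are no negatives).
#'
#' @param result a [SearchResult-class].
#' @return named numeric: `precision`, `fpr`, `tp`, `fp`, `negatives`.
#' @export
screeningStats <- function(result) {
  tp <- length(result@verified)
  fp <- length(result@candidates) - tp - length(result@undecided)
  negatives <- result@corpusSize - tp
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  fpr <- if (negatives <= 0) 0 else fp / negatives
  c(precision = precision, fpr = fpr, tp = tp, fp = fp, negatives = negatives)
}

#' Evaluate a query set against an index
#'
#' @param index an [InvertedIndex-class].
#' @param queries list of [Molecule-class] (optionally named).
#' @param sel [selectionParams].
#' @param opts [matchOptions].
#' @return list with `perQuery` (data.frame: one row per query with
#'   candidate/verified counts, precision, fpr, selected-bit count) and
#'   `summary` (median fpr and precision, plus the fraction of queries with
#'   fpr below 1e-1 .. 1e-3).
#' @export
evaluateQueries <- function(index, queries, sel = selectionParams(),
                            opts = matchOptions()) {
  qnames <- names(queries)
  rows <- lapply(seq_along(queries), function(i) {
    res <- suppressWarnings(searchSubstructure(index, queries[[i]], sel, opts))
    st <- screeningStats(res)
    data.frame(query = if (!is.null(qnames) && nzchar(qnames[i])) qnames[i]
               else paste0("Q", i),
               candidates = length(res@candidates),
               verified = length(res@verified),
               undecided = length(res@undecided),
               selectedBits = length(res@plan$selectedBits),
               precision = st[["precision"]], fpr = st[["fpr"]])
  })
  perQuery <- do.call(rbind, rows)
  thresholds <- c(1e-1, 1e-2, 1e-3)
  summary <- list(
    medianFpr = stats::median(perQuery$fpr),
    medianPrecision = stats::median(perQuery$precision),
    fprBelow = vapply(thresholds, function(t) mean(perQuery$fpr < t), numeric(1))
  )
  names(summary$fprBelow) <- paste0("fpr<", thresholds)
  list(perQuery = perQuery, summary = summary)
}
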