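# VF2-style subgraph isomorphism with substructure-search semantics. The
# query may be multi-fragment; one global injective mapping of the whole
# query graph is required, so n benzene-ring fragments cannot all map into a
# target that only accommodates n-1 non-overlapping rings.

#' Matching options
#'
#' @param chargeSensitive compare formal charges (default TRUE).
#' @param isotopeSensitive compare isotopes when the query atom specifies one
#'   (default TRUE; query atoms with unspecified isotope never constrain).
#' @param limit optional positive cap on explored search states; when
#'   exceeded the outcome is "undecided" rather than a wrong answer.
#' @return list with class `MatchOptions`.
#' @export
matchOptions <- function(chargeSensitive = TRUE, isotopeSensitive = TRUE,
                         limit = NULL) {
  if (!is.null(limit)) stopifnot(is.numeric(limit), length(limit) == 1, limit > 0)
  structure(list(chargeSensitive = isTRUE(chargeSensitive),
                 isotopeSensitive = isTRUE(isotopeSensitive),
                 limit = limit), class = "MatchOptions")
}

#' Atom compatibility under substructure-search semantics
#'
#' A query atom is compatible with a target atom iff the elements are equal,
#' charges are equal (when charge-sensitive), isotopes are equal when the
#' query specifies one, aromatic flags are equal, and the target hydrogen
#' count is at least the query's when the query count was bracket-specified.
#'
#' @param q,t single-row atom tables (as from `atoms(mol)[i, ]`).
#' @param opts a [matchOptions] list.
#' @return logical.
#' @export
atomsCompatible <- function(q, t, opts = matchOptions()) {
  if (q$element != t$element) return(FALSE)
  if (opts$chargeSensitive && q$charge != t$charge) return(FALSE)
  if (opts$isotopeSensitive && !is.na(q$isotope) &&
      (is.na(t$isotope) || q$isotope != t$isotope)) return(FALSE)
  if (q$aromatic != t$aromatic) return(FALSE)
  if (q$hexplicit && t$hcount < q$hcount) return(FALSE)
  TRUE
}

.runMatch <- function(query, target, opts, findAll) {
  q <- .molToC(query); t <- .molToC(target)
  cpp_match(q$elem, q$chg, q$iso, q$arom, q$h, q$hexp,
            q$bf, q$bt, q$bo, q$ba,
            t$elem, t$chg, t$iso, t$arom, t$h, t$hexp,
            t$bf, t$bt, t$bo, t$ba,
            opts$chargeSensitive, opts$isotopeSensitive,
            findAll, if (is.null(opts$limit)) 0 else as.numeric(opts$limit))
}

#' Is the query a substructure of the target?
#'
#' TRUE iff at least one embedding (injective atom mapping preserving atom
#' and bond compatibility) exists. Aromatic query bonds match only aromatic
#' target bonds; non-aromatic query bonds match non-aromatic target bonds of
#' equal order - no Kekule-to-aromatic bridging is performed.
#'
#' @param query,target [Molecule-class] objects.
#' @param opts a [matchOptions] list.
#' @return TRUE, FALSE, or NA when the state limit was exceeded (undecided).
#' @examples
#' isSubstructure(parseSmiles("c1ccccc1"), parseSmiles("Cc1ccccc1"))
#' @export
isSubstructure <- function(query, target, opts = matchOptions()) {
  res <- .runMatch(query, target, opts, findAll = FALSE)
  if (res$exceeded && res$count == 0) return(NA)
  res$count > 0
}

#' Count all embeddings of a query in a target
#'
#' The exact number of distinct injective atom mappings; automorphic
#' variants are counted separately (a benzene query embeds in a benzene
#' target 12 ways).
#'
#' @inheritParams isSubstructure
#' @return non-negative integer count.
#' @examples
#' b <- parseSmiles("c1ccccc1")
#' countEmbeddings(b, b)  # 12
#' @export
countEmbeddings <- function(query, target, opts = matchOptions()) {
  res <- .runMatch(query, target, opts, findAll = TRUE)
  if (res$exceeded) stop("state limit exceeded while counting embeddings")
  as.integer(res$count)
}
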