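# Inverted index over fingerprint keywords: each 36-bit FeatureId becomes a
# 6-character base64 term whose posting list holds the ordinals of the
# compounds containing the bit. A single-directory on-disk format (text
# manifest + vocabulary, varint delta-encoded postings, SMILES compound
# store) replaces an external text-search engine while honouring the same
# keyword contract.

.B64 <- c(LETTERS, letters, as.character(0:9), "+", "/")  # RFC 4648 table
.INDEX_FORMAT_VERSION <- 1L

#' Encode a 36-bit FeatureId as a 6-character base64 keyword
#'
#' The value is split big-endian into six 6-bit groups, each mapped through
#' the standard RFC 4648 base64 alphabet; the mapping is injective on the
#' 36-bit domain.
#'
#' @param bit numeric vector of FeatureId values in `[0, 2^36)`.
#' @return character vector of 6-character keywords.
#' @examples
#' encodeKeyword(c(0, 1, 2^36 - 1))  # "AAAAAA" "AAAAAB" "//////"
#' @export
encodeKeyword <- function(bit) {
  bit <- as.numeric(bit)
  if (any(is.na(bit) | bit < 0 | bit >= 2^36 | bit != floor(bit)))
    stop("FeatureId out of 36-bit range")
  out <- character(length(bit))
  for (i in seq_along(bit)) {
    v <- bit[i]
    g <- integer(6)
    for (k in 6:1) { g[k] <- v %% 64; v <- v %/% 64 }
    out[i] <- paste(.B64[g + 1L], collapse = "")
  }
  out
}

#' Decode a 6-character base64 keyword back to its 36-bit FeatureId
#' @param keyword character vector of 6-character keywords.
#' @return numeric vector of FeatureId values.
#' @export
decodeKeyword <- function(keyword) {
  vapply(keyword, function(kw) {
    g <- match(strsplit(kw, "")[[1]], .B64) - 1L
    if (length(g) != 6 || anyNA(g)) stop("malformed keyword: ", kw)
    sum(g * 64^(5:0))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build an inverted index from molecules
#'
#' Every compound is fingerprinted; for each of its bits the compound's
#' 0-based ordinal is appended to the bit's keyword posting list. Records
#' whose value is an error placeholder (from [readSmilesFile] accounting)
#' are not possible here since the input is already parsed; pass the result
#' of [readSmilesFile] to index a file including its failure count.
#'
#' @param records named list of [Molecule-class] (names are identifiers,
#'   must be unique), or the list returned by [readSmilesFile].
#' @param params [fingerprintParams].
#' @param outPath optional directory; when given the index is persisted
#'   there via [saveIndex].
#' @return an [InvertedIndex-class].
#' @export
buildIndex <- function(records, params = fingerprintParams(), outPath = NULL) {
  failures <- 0L
  if (!is.null(records$molecules) && !inherits(records, "Molecule")) {
    failures <- records$failures
    records <- records$molecules
  }
  ids <- names(records)
  if (length(records) && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    stop("records must be uniquely named by identifier")
  postings <- new.env(parent = emptyenv())
  store <- vector("list", length(records))
  for (i in seq_along(records)) {
    mol <- records[[i]]
    stopifnot(is(mol, "Molecule"))
    store[[i]] <- mol
    ord <- i - 1L
    kws <- encodeKeyword(featureIds(fingerprint(mol, params)))
    for (kw in kws) postings[[kw]] <- c(postings[[kw]], ord)
  }
  idx <- new("InvertedIndex",
             manifest = list(formatVersion = .INDEX_FORMAT_VERSION,
                             graphSize = params$graphSize,
                             n = length(records),
                             ids = as.character(ids %||% character()),
                             failures = failures),
             postings = postings, store = store)
  if (!is.null(outPath)) saveIndex(idx, outPath)
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screening candidates for a set of fingerprint bits
#'
#' Intersects the posting lists of the given bits. A bit absent from the
#' vocabulary contributes an empty list (so the result is empty); an empty
#' bit set returns all ordinals.
#'
#' @param index an [InvertedIndex-class].
#' @param bits numeric vector of FeatureId values (or a [FeatureSet-class],
#'   whose bit ids are used).
#' @return sorted integer vector of 0-based candidate ordinals.
#' @export
candidates <- function(index, bits) {
  if (is(bits, "FeatureSet")) bits <- featureIds(bits)
  n <- index@manifest$n
  if (!length(bits)) return(if (n > 0) 0:(n - 1L) else integer())
  kws <- unique(encodeKeyword(bits))
  lists <- lapply(kws, function(kw) index@postings[[kw]] %||% integer())
  res <- lists[[which.min(lengths(lists))]]
  for (pl in lists) {
    res <- intersect(res, pl)
    if (!length(res)) return(integer())
  }
  sort(as.integer(res))
}

#' Per-bit document frequencies of an index
#'
#' @param index an [InvertedIndex-class].
#' @return an [OccurrenceTable-class] (frequency = number of compounds whose
#'   fingerprint contains the bit, keyed by keyword).
#' @export
occurrenceTable <- function(index) {
  kws <- ls(index@postings)
  freq <- vapply(kws, function(kw) length(index@postings[[kw]]), numeric(1))
  new("OccurrenceTable", frequency = freq, total = as.integer(index@manifest$n))
}

# occurrence table restricted to the given bits: cheap per-query lookup
# (absent keywords get frequency 0, which occurrence() also reports)
.occurrenceFor <- function(index, ids) {
  kws <- unique(encodeKeyword(ids))
  freq <- vapply(kws, function(kw) length(index@postings[[kw]]), numeric(1))
  freq <- freq[freq > 0]
  new("OccurrenceTable", frequency = freq,
      total = as.integer(index@manifest$n))
}

#' Relative occurrence (inverse filtering power) of bits
#'
#' @param table an [OccurrenceTable-class].
#' @param bit numeric vector of FeatureId values.
#' @return fractions in `[0, 1]`; bits never seen give 0.
#' @export
occurrence <- function(table, bit) {
  if (table@total == 0L) stop("occurrence undefined for an empty corpus")
  kws <- encodeKeyword(bit)
  f <- table@frequency[kws]
  f[is.na(f)] <- 0
  unname(f) / table@total
}

#' Persist an inverted index to a directory
#'
#' Writes `manifest.json` (format version, parameters, identifier/ordinal
#' mapping), `vocab.tsv` (keyword, byte offset, byte length, document
#' frequency), `postings.bin` (concatenated varint-encoded delta posting
#' lists) and `store.smi` (SMILES + identifier per ordinal).
#'
#' @param index an [InvertedIndex-class].
#' @param path directory to create/overwrite.
#' @export
saveIndex <- function(index, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  kws <- sort(ls(index@postings))
  blobs <- lapply(kws, function(kw) cpp_varint_encode(index@postings[[kw]]))
  sizes <- vapply(blobs, length, integer(1))
  offsets <- c(0L, cumsum(sizes))[seq_along(kws)]
  vocab <- data.frame(keyword = kws, offset = offsets, nbytes = sizes,
                      docfreq = vapply(kws, function(kw)
                        length(index@postings[[kw]]), integer(1)))
  jsonlite::write_json(index@manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(vocab, file.path(path, "vocab.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(path, "postings.bin"), "wb")
  on.exit(close(con))
  for (bl in blobs) if (length(bl)) writeBin(bl, con)
  lines <- vapply(seq_along(index@store), function(i)
    paste(writeSmiles(index@store[[i]]), index@manifest$ids[i], sep = "\t"),
    character(1))
  writeLines(lines, file.path(path, "store.smi"))
  invisible(path)
}

#' Load an inverted index from a directory
#'
#' Fails with an explicit incompatibility error on a format-version
#' mismatch and with an integrity error on a truncated postings file;
#' `load(save(x))` is observationally identical to `x`.
#'
#' @param path directory written by [saveIndex].
#' @return an [InvertedIndex-class].
#' @export
loadIndex <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not an index directory (no manifest): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$formatVersion) ||
      manifest$formatVersion != .INDEX_FORMAT_VERSION)
    stop("incompatible index format version: ",
         manifest$formatVersion %||% "<missing>")
  manifest$n <- as.integer(manifest$n)
  manifest$graphSize <- as.integer(manifest$graphSize)
  manifest$ids <- as.character(manifest$ids)
  vocab <- utils::read.table(file.path(path, "vocab.tsv"), sep = "\t",
                             header = TRUE, colClasses = c("character",
                             "integer", "integer", "integer"))
  pfile <- file.path(path, "postings.bin")
  need <- if (nrow(vocab)) max(vocab$offset + vocab$nbytes) else 0L
  raw <- readBin(pfile, "raw", n = file.info(pfile)$size)
  if (length(raw) < need) stop("postings file integrity error: truncated")
  postings <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(vocab))) {
    bl <- raw[seq.int(vocab$offset[i] + 1L, length.out = vocab$nbytes[i])]
    pl <- cpp_varint_decode(bl)
    if (length(pl) != vocab$docfreq[i] || is.unsorted(pl, strictly = TRUE))
      stop("postings file integrity error: corrupt posting list for ",
           vocab$keyword[i])
    postings[[vocab$keyword[i]]] <- pl
  }
  lines <- readLines(file.path(path, "store.smi"), warn = FALSE)
  if (length(lines) != manifest$n)
    stop("store integrity error: expected ", manifest$n, " compounds")
  store <- lapply(lines, function(line)
    parseSmiles(strsplit(line, "\t", fixed = TRUE)[[1]][1]))
  new("InvertedIndex", manifest = manifest, postings = postings, store = store)
}
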