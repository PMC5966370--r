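Package: MolScreen
Title: Substructure Search by Substructural Fingerprint Screening and
    Subgraph Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained chemical substructure search engine. Molecules
    are read from SMILES, decomposed into substructural fingerprint features
    (atom types, smallest-set-of-smallest-rings ring patterns, and all
    connected subgraphs with at most one ring up to a bond limit), hashed to
    36-bit identifiers and stored as 6-character base64 keywords in an
    inverted index. Queries are reduced by subsumption and by a
    filtering-power bit-selection algorithm, screened against the posting
    lists, and verified with a VF2-style subgraph-isomorphism matcher.
    Includes a deterministic synthetic molecule generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
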