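Package: kbindr
Title: Stratified Analysis and Prediction of TCR Cross-Reactivity from
    Display-Panning Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how T-cell receptor (TCR) CDR3 sequences
    encode cross-reactivity against a small universe of related
    peptide-MHC targets.  Simulates multi-round display-panning read-count
    data over a randomized six-residue CDR3 library, calls binders from
    round-3 presence in replicate selections, stratifies variants by
    k-binding (the number of targets bound), builds per-stratum sequence
    logos, tests observed cross-reactivity against an independent-binding
    null, trains multi-label neural binding classifiers on BLOSUM50, VHSE8
    or one-hot sequence embeddings with square-root stratum-weighted
    sampling, and ranks CDR3 residue importance by masked retraining,
    optionally correlating the resulting importance with externally
    computed interface-energy changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
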