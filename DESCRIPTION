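Package: afseq
Title: Alignment-Free Protein Sequence Descriptors and Enzyme Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free featurization of protein sequences and a complete
    enzyme/non-enzyme classification workflow. Computes composition (0D) and
    sequence-order (1D) descriptors by encoding residues with amino-acid
    property indices, applying the electrotopological-state vicinity operator,
    grouping residues by physicochemical class and aggregating with invariant
    operators; computes pseudo-fold (2D) descriptors as spectral moments of
    weighted graphs obtained from a Nandy lattice embedding of the sequence.
    Includes a three-stage feature-selection pipeline (information-gain filter,
    single-linkage Spearman redundancy clustering, genetic-search wrapper), a
    Pearson VII universal kernel (PUK) support vector machine with logistic
    probability calibration, repeated stratified cross-validation, a synthetic
    labelled-sequence generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    kernlab,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
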