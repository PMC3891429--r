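Package: sltk
Title: Sliding Tree Kernel for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the sliding tree kernel, a subset-tree convolution
    kernel computed between per-token windowed parse-tree fragments, each
    augmented with a current-word marker node so that fragments centred on
    different tokens of one sentence are structurally distinct.  Around the
    kernel the package provides a complete support-vector-machine BIO tagger
    for biomedical named entity recognition: bracketed-tree and flat
    part-of-speech tree construction, brute-force fragment enumeration
    oracles, Gram-matrix assembly over precomputed kernels, one-vs-all
    classification, JNLPBA-dialect corpus input/output, entity-level
    precision/recall/F evaluation, and a seeded generator of synthetic
    annotated corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    kernlab,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
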