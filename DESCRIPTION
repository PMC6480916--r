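Package: tdnascope
Title: Reconstruction of T-DNA Integration Architectures from Long Reads
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transgene (T-DNA) insertion sites, reconstructs
    multi-fragment T-DNA concatemers, chromosomal translocations,
    truncations and deletions from long sequencing reads of a mutant and
    a control sample. Includes a deterministic rearranged-genome and long
    read simulator with a machine-readable truth set, a built-in
    seed-chain-extend local aligner (plus PAF/SAM ingestion), split-read
    breakpoint clustering, non-homologous end-joining junction signature
    classification (micro-homology, filler DNA, long homology), binned
    read-depth copy-loss calling, and an end-to-end reproducible pipeline
    with a rearrangement report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
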