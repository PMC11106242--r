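Package: m6adscan
Title: Predict Variants That Alter Accessibility of Distal mRNA m6A Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide screen for single-nucleotide variants that change the
    base-pairing state (accessibility) of distal DRACH m6A motifs in the
    CDS-terminal hotspot of mRNAs. For each variant joined to a validated m6A
    site, the package builds a spliced analysis window covering the last two
    coding exons and the head of the 3'UTR (capped at 250 nt), applies coding
    consequence filters, folds reference and alternate windows to their
    minimum-free-energy secondary structure under a no-lonely-pairs
    constraint, and scores DRACH-segment pairing with a non-overlapping
    counter scheme to detect structure-switch (riboSNitch-like) candidates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA RNAfold (optional, for the 'vienna' folding
    engine); the built-in engine has no external requirements.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
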