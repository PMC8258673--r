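Package: trfclash
Title: Binding-Motif Discovery for tRNA-Derived Fragments from Chimeric
    CLASH Reads, PAR-CLIP Conversions and icSHAPE Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes two-orientation chimeric (CLASH-style) reads into
    tRNA-derived fragment (tRF) guides and their ligated targets, classifies
    tRFs into the six coordinate-based types with canonical names, detects and
    partitions polyT library artifacts by dinucleotide-composition analysis,
    discovers per-tRF target binding motifs with a ZOOPS
    expectation-maximisation position-weight-matrix finder calibrated against
    dinucleotide-shuffled decoys, matches motifs back onto guides with an
    exact convolution-based p-value, profiles Argonaute crosslinking sites
    from PAR-CLIP T-to-C conversions, classifies target secondary structure
    from icSHAPE-style reactivity, and generates fully synthetic inputs with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
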