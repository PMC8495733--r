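Package: sonichip
Title: Chromatin Sonication, Fragment Size and ChIP-seq Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating sheared-chromatin fragment length to
    ChIP-seq data quality. Measures average chromatin length from
    Bioanalyzer-style electropherogram traces, fits and inverts the
    exponential decay of fragment size with sonication cycles, computes
    strand cross-correlation quality metrics (NSC, RSC, fragment-length
    estimate), FRiP and high-confidence FRiP scores, classifies peaks as
    direct or indirect binding by position-weight-matrix scanning with
    exact dynamic-programming p-value thresholds, builds peak-centered
    metapeak matrices and profiles, and applies rule-based pass/low-pass/
    fail assessment with size-binned group testing. Includes a synthetic
    ChIP-seq simulator in which immunoprecipitation efficiency depends on
    fragment length (epitope occlusion on long fragments, binding-site
    destruction on short ones), so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
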