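Package: cnpurity
Title: Tumour Purity Estimation and Purity-Adjusted Copy Number Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tumour purity from single-cell detection tables
    restricted to pathologist-annotated regions of interest, adjusts
    segmented copy number profiles for tumour content by two-component
    tumour/normal mixture inversion, classifies segments and chromosome
    arms into loss/neutral/gain, computes the whole genome instability
    index (WGII), and cross-tabulates arm-level calls between
    purity-estimation methods with under-/over-calling statistics. A
    synthetic-cohort generator emulates segmented tumour/normal mixtures
    at known purity together with method-specific biased purity
    observers, paired serial-section replicates, and cell point
    patterns, so the whole chain is testable without access to cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
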