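Package: repliwave
Title: Chromosomal Wave Analysis of Base-Pair Substitution Rates from
    Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the spatial pattern of base-pair
    substitution (BPS) rates along circular bacterial chromosomes, as
    measured in mutation-accumulation (MA) experiments.  Provides
    origin-anchored circular binning by replichore, per-generation
    mutation-rate estimation with bootstrap confidence limits,
    Daubechies wavelet smoothing of binned series, Morlet wavelet
    coherence with cone of influence and phase for clockwise versus
    counterclockwise symmetry analysis, region-stratified Pearson
    correlation tables with Benjamini-Hochberg adjustment, trinucleotide
    mutation-context classification and hot-spot filtering, and a
    seeded synthetic MA-data generator with known position-dependent
    mutation intensity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR
Config/testthat/edition: 3
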