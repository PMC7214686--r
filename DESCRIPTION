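Package: promshape
Title: Promoter Classification by H3K4me1 Peak-Density Shape Around Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates ChIP-seq peak calls (BED/narrowPeak/broadPeak) against a
    transcription start site (TSS) catalogue and classifies promoters by the
    shape of the H3K4me1 peak-density distribution around the TSS: a single
    TSS-centered mode marks poised (H3K4me3/H3K27me3 bivalent) promoters,
    while two modes flanking the TSS 300-1000 bp away mark epigenetically
    active promoters. Provides strand-aware signed nearest-neighbor distance
    queries, Gaussian kernel density profiles of peak placement, bivalent
    peak-overlap classification rules, TPM expression binning, a tie-corrected
    Kruskal-Wallis rank test, a seeded synthetic chromatin-landscape generator
    with ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
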