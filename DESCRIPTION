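Package: chromshape
Title: Shape-Based Comparison of Chromatin Occupancy Profiles
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative, per-gene comparison of chromatin occupancy
    profiles (nucleosomes from MNase-seq, chromatin remodelers and RNA
    polymerase II from ChIP-seq) between two samples. Occupancy over each
    transcribed region (TSS to polyadenylation site) is binned at 10 bp,
    smoothed with a cubic spline, and the per-gene Pearson correlation
    between samples is computed genome-wide ('shapeDiff'). Also provides
    anchor-aligned metagene profiles with 95% confidence bands (TSS- or
    intron-junction-aligned), transcription-rate gene-set construction,
    Flag/Myc histone-exchange ratio tracks, coverage-track utilities, and a
    seeded synthetic-data generator emulating phased nucleosome arrays,
    polymerase pausing at intron junctions, and two-tag exchange data, so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
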