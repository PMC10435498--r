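Package: SiameseHiC
Title: Replicate-Aware Siamese Metric Learning for Differential Chromatin
    Conformation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns a distance metric over windowed Hi-C / Micro-C contact
    maps with a twin (Siamese) convolutional network trained by contrastive
    learning on replicate pairs (technical noise) versus condition pairs
    (biological change). Provides contact-matrix input with ICE balancing,
    diagonal window extraction and cleaning, labelled pair assembly with
    chromosome-held-out splits, CPU training of the shared-weight encoder
    with a cross-embedding regulariser, separation statistics (overlap
    threshold, mean performance, separation index), convolutional-filter
    difference maps with replicate-calibrated feature calling, and a
    synthetic multi-replicate Hi-C experiment generator with a planted
    truth table so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: HiC, Epigenetics, Software, DifferentialChromatinConformation
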