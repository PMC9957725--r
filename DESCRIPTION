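Package: utrscape
Title: Promoter Architecture and 5'UTR Isoform Translational Landscape from CAGE TSS Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse the translational landscape of alternative 5'UTR
    isoforms from CAGE-style transcription start site (CTSS) count data and a
    genome. Implements distance clustering of CTSS positions into tag clusters,
    quantile promoter widths with sharp/broad classification, the TOPscore
    metric over TSS heterogeneity, PRTE motif scoring of reconstructed 5' reads,
    polysome heavy/light translational-efficiency readouts and TSS-window
    switches, gene-level translational efficiency with Kolmogorov-Smirnov
    comparison, differential tag-cluster usage with Benjamini-Hochberg
    correction, the mTORC1-dependency reporter statistic, 5'UTR sequence
    features (NUG/uORF counts, GC content, a maximum base-pairing folding
    proxy), and isoform-level PSI survival stratification with Kaplan-Meier,
    log-rank and univariate Cox analyses. A synthetic-data generator with
    planted promoter classes, motifs and effect sizes provides a fully
    self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
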