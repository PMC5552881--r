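Package: cernascan
Title: Probabilistic Prediction of Competing Endogenous RNAs from miRNA
    Response Element Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts and ranks candidate competing endogenous RNAs (ceRNAs)
    of a chosen target gene from the locations of miRNA response elements
    (MREs) on 3' UTRs. Groups miRNAs into seed families, scans UTR sequences
    for high-affinity seed-match sites (7mer-m8, 7mer-A1, 8mer), optionally
    restricted to CLIP peak intervals, and computes five analytical
    significance features per candidate: binomial enrichment of shared MREs,
    hypergeometric enrichment of shared miRNA families, and three order-
    statistic tests on the spatial arrangement of shared sites (span,
    successive distances, evenness). Features are computed in both
    directions of the gene/candidate pair, combined reciprocally, and turned
    into a score with empirical p-values. Includes a uniform-placement null
    simulator with Kolmogorov-Smirnov feature-relevance checks, a
    shuffled-UTR uniformity check, and a synthetic fixture generator with
    planted ceRNAs for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    stats,
    tibble,
    utils,
    jsonlite
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
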