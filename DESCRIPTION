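Package: alleloop
Title: Single-Allele Chromatin Contact and Optogenetic Clustering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of single-allele chromatin looping from
    high-throughput DNA/RNA-FISH imaging tables and of light-induced protein
    clustering from masked nuclear images. Provides the coefficient-of-variation
    clustering statistic and half-maximal clustering/declustering times,
    Fourier phase-correlation registration of sequential imaging rounds,
    nucleus quality-control and ploidy filtering, greedy one-to-one
    cross-channel spot matching with distance-threshold contact calling,
    per-cell transcription-site summaries and equal-count binning, the
    binomial allele-independence null with a Pearson chi-square test, and the
    Marascuilo procedure for multiple proportions. A synthetic-data module
    generates nucleus/spot tables, cluster images and kinetic traces with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
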