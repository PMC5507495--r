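Package: seedlong
Title: Seed Longevity Acquisition from Storage Viability and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the acquisition of seed longevity during
    late maturation. Fits logistic loss-of-viability curves to storage
    germination assays and derives the P50 longevity statistic; normalizes
    RNA-seq count matrices (median-of-ratios size factors), filters by
    log-scale variance, and tests differential expression with a negative
    binomial Wald approximation; builds a Pearson-correlation-thresholded
    transcription factor co-expression network with trait-based gene
    significance against P50 and extracts the longevity module; provides
    chi-square family enrichment, hypergeometric GO over-representation,
    bin-wise Wilcoxon enrichment with z-score conversion, Venn contrast
    algebra, and comparative 2^-ddCt qPCR quantification. Includes a seeded
    synthetic-data generator with planted ground truth so every stage of the
    pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
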