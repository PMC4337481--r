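Package: dcTFnet
Title: Weighted Transcription Factor Regulatory Networks from Differential
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate transcription factors (TFs) from two-group
    expression studies by weighting TF-target edges with within-group Spearman
    correlations, filtering edges against a permutation null of the differential
    coefficient, scoring each hub TF's subnetwork with a weighted running-sum
    enrichment score with leading-edge trimming, and ranking TFs by a combined
    Z-score that joins edge-level and gene-level enrichment. Includes a
    moderated two-sample t-test for differential expression, hypergeometric
    over-representation analysis against GMT gene-set collections, a synthetic
    data generator with planted fold changes and planted differential
    co-regulation, and an end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
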