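Package: qpcrStability
Title: Reference Gene Stability Assessment for qRT-PCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screening and stability ranking of candidate reference genes
    for quantitative real-time PCR normalization. Candidates are screened
    from an RNA-seq abundance matrix by an expression window together with
    coefficient-of-variation and maximum-fold-change filters, then ranked
    from replicate Ct tables by three complementary stability algorithms
    (geNorm pairwise-variation M values with the V(n/n+1) criterion, a
    NormFinder-style inter/intra-group variance model, and BestKeeper-style
    index correlation), and finally combined into a consensus ranking.
    Includes a synthetic-data generator with planted stability structure
    for validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
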