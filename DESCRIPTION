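Package: pathbn
Title: Differential Analysis of Pathway-Structured Bayesian Networks Across
    Expression Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies altered genes and gene-gene relationships between a
    disease and a control group by treating curated signaling pathways as the
    fixed structure of linear-Gaussian Bayesian networks. For every gene the
    conditional mean is a linear regression on its pathway parents; the
    intercept is the gene's node parameter and each parent coefficient is an
    edge parameter. Networks are trained per group on expression data that has
    been quantile normalized, intersection-merged within platform, and
    batch-adjusted with empirical-Bayes ComBat. Case-minus-control parameter
    contrasts are tested per platform with Welch-type Wald statistics under
    Benjamini-Hochberg false-discovery-rate control, and the surviving
    per-platform contrasts are combined by a subject-count-weighted mixture
    model whose standardized mean scores each final parameter. Includes KGML
    and SIF pathway readers, a linear structural-equation simulator with batch
    effects and gene dropout for validation, and an end-to-end pipeline with
    TSV/GraphML exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    igraph,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
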