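Package: coexmod
Title: Gene Co-Expression Network Modules Associated with a Quantitative Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gene co-expression modules in bulk RNA-Seq data and tests
    their single-sample enrichment scores for association with a quantitative
    phenotype such as clinician-rated depression severity. Implements the full
    workflow: low-count filtering and logCPM normalization, angle-based outlier
    detection, batch-effect removal, coefficient-of-variation filtering,
    hard-thresholded unsigned correlation networks with topological overlap
    dissimilarity, average-linkage clustering with an adaptive (dynamic) tree
    cut, single-sample gene set enrichment scoring (ssGSEA), covariate-adjusted
    linear association with Benjamini-Hochberg false discovery rate control,
    eigenvector-centrality hub analysis, and scoring of an independent cohort
    for replication. Ships a negative-binomial synthetic-cohort generator with
    planted module structure so the whole pipeline is testable without access
    to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
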