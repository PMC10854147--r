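Package: gsThemes
Title: Higher-Order Biological Theme Discovery from Gene-Set Enrichment Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Summarises gene-set enrichment results into higher-order
    biological themes. Pairwise gene-set similarity (adjusted Rand index,
    Jaccard index, overlap coefficient) over the measured-gene universe is
    thresholded into a gene-set overlap graph; walktrap community detection
    identifies clusters of related gene-sets which are prioritised with a
    product-of-ranks statistic, annotated with TF-IDF keyword tables mined
    from gene-set names or descriptions, characterised at the gene level by
    membership frequency against experimental statistics, and contextualised
    with induced protein-protein interaction subnetworks. A rank-based
    (singscore-style) scoring module links factor loadings (e.g. PCA of
    single-cell or spatial transcriptomics data) to gene-sets for
    unsupervised phenotype discovery, and a synthetic collection generator
    with planted theme structure supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
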