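Package: citerank
Title: PageRank-Based Importance Ranking of Citation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts PMID citation networks from PMC/JATS full-text article
    XML, computes PageRank over the resulting directed graph by power
    iteration (damping 0.85, convergence tolerance 1e-5), builds the inverted
    citation index of inbound citations per article, and reproduces a
    correlation-based validation of PageRank against raw citation counts:
    seeded random sampling, Pearson correlation, simple linear regression,
    finite-population sample-size calculation, and top-N ranking tables. A
    preferential-attachment (Price model) simulator generates synthetic
    citation corpora, including JATS fixture files, so the full pipeline is
    exercisable without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'analysis.R'
    'citerank-package.R'
    'cli.R'
    'graph.R'
    'jats.R'
    'methods-accessors.R'
    'pagerank.R'
    'synthetic.R'
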