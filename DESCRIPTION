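Package: genepheno
Title: Sentence-Level Gene-Phenotype Association Mining from Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A text mining pipeline for extracting sentence-level gene-phenotype
    co-mentions from full-text article XML (JATS/PMC dialect). Builds a phenotype
    lexicon from UMLS-style RRF files via two-layer source-vocabulary and
    semantic-type filtering, detects gene and phenotype mentions per sentence,
    standardizes phenotypes against a priority-ordered multi-vocabulary lexicon
    with Human Phenotype Ontology top-level category assignment, scores
    associations with normalized pointwise mutual information (NPMI), clusters
    gene phenotype profiles (t-SNE + k-means with concordance metrics), and
    builds a phenotype-sharing gene interaction network ranked by betweenness
    centrality. Includes a synthetic corpus generator with planted co-occurrence
    structure for offline validation, and an evaluation harness against gold
    annotations and reference association databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    stringi,
    Rtsne,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
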