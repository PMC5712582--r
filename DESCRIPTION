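Package: ccrel
Title: Cell-Cytokine Relation Extraction and Knowledge Graphs from Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A distant-supervision pipeline that recognizes cell and cytokine
    mentions in biomedical abstracts by exact dictionary matching, pairs them
    within sentences, labels the resulting co-occurrence bags against a
    reference relation database, classifies bags with a sparse multi-instance
    learning (sMIL) linear max-margin classifier over tf-idf context features,
    and emits an evidence-backed bipartite cell-cytokine knowledge graph with
    cross-validation, graph-comparison and manual-curation tooling. Includes a
    seedable synthetic corpus generator with planted relations so the whole
    pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    igraph,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    withr
Config/testthat/edition: 3
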