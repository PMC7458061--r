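Package: docgraphre
Title: Document-Level Chemical-Disease Relation Extraction with Graph
    Convolution and Multihead Attention
Version: 0.1.0
Authors@R:
    person("docgraphre", "maintainers", email = "docgraphre@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for document-level chemical-induced
    disease (CID) relation extraction from PubMed-style abstracts.  Reads
    PubTator corpora and CoNLL-U dependency parses, constructs labeled
    intrasentence and intersentence candidate instances with nearest-mention
    heuristics, builds a document-level dependency graph (syntactic edges,
    adjacent-sentence root edges, self-loops), and classifies candidate
    pairs with a BiLSTM encoder combined with multihead self-attention and
    a graph convolutional network over the document graph.  Includes a
    deterministic synthetic-corpus generator with planted decision rules so
    that every stage, including end-to-end training, is testable at desk
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
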