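Package: docgraphRE
Title: Document-Subgraph Relation Extraction for Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts intra- and inter-sentence chemical-induced disease (CID)
    relations from annotated biomedical abstracts. Dependency trees of the title
    plus a sliding window of consecutive sentences are merged into document
    subgraphs and augmented with labeled virtual edges (TITLE, NEXT-SENT,
    coreference and knowledge-base links); bounded breadth-first search mines
    multiple dependency paths between entity mention heads, which are merged,
    deduplicated and pruned to the top-k per concept pair; a shared-weight
    convolutional network with attentive child-context augmentation classifies
    each pair. Includes readers and writers for the PubTator and CoNLL-U corpus
    dialects, a synthetic corpus generator for end-to-end testing, and an
    evaluation harness reporting micro precision/recall/F1 split into intra- and
    inter-sentence relations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
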