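Package: litcooc
Title: Co-Occurrence Mining of Gene and Protein Interactions from
    Literature Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts candidate gene/protein interactions from collections
    of biomedical abstracts by dictionary-based entity tagging and
    sentence-level co-occurrence analysis. Every co-occurring bioentity
    pair is classified into one of four confidence types depending on the
    position of biointeraction trigger words relative to the entity names,
    sentences mentioning four or more distinct bioentities are excluded as
    too complex, and co-occurrences are associated with user-defined
    biological concepts found in the same sentence (or abstract, for
    abstract-level pairs). The resulting typed, evidence-carrying
    interaction network can be filtered by confidence type or concept and
    exported to GraphML, SIF or TSV. An evaluation bench scores predicted
    pairs against gold-standard interaction sets with a pooled-truth
    protocol, including recall stratification by entity-recognition
    failure mode, and a deterministic fixture generator plants known
    interaction structure so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    purrr,
    rlang,
    stringi,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
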