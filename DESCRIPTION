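Package: polykb
Title: Polymorphic-Reference Knowledgebase Prototyping Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embeddable engine for prototyping precision-medicine
    knowledgebases with runtime-defined schemas. Any reference field can
    link to a record in any table through a polymorphic foreign key (a
    stored pair of table identifier and record identifier), so new
    knowledge categories are added as new tables plus reference rewiring
    with no modification of existing table structures. Supports interactive
    alternation between schema curation and content entry, batch integrity
    validation with machine-readable violations, transactional schema
    evolution, mind-map document serialization, flow traversal, DOT graph
    rendering, relational (SQLite-compatible) export/import, and a
    session-file command-line interface. Ships a worked clinical
    decision-support example encoding a thiopurine (6-mercaptopurine,
    TPMT/NUDT15) pharmacogenomic dosing flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    rlang,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
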