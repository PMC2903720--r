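Package: OntoRecommender
Title: Ontology Recommendation by Dictionary-Based Concept Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained engine that recommends biomedical ontologies
    for a text corpus or keyword list. It compiles a term dictionary from an
    OBO-format ontology repository (preferred names and synonyms), produces
    direct annotations by syntactic concept recognition with longest-only
    span suppression, optionally expands annotations through cross-ontology
    point-to-point mappings or the is_a hierarchy, assigns context weights
    to annotations, and ranks ontologies by aggregate score or
    size-normalized score. Includes a pinned worked-example repository and a
    seeded synthetic repository/corpus generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
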