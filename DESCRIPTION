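Package: cohortkg
Title: Ontology-Aligned Knowledge Graphs for Multi-Source Neuro-Assessment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous per-study tables of neuropsychological
    assessment scores and image-derived volumetric features into an
    OBO-Foundry-aligned RDF knowledge graph, selects study cohorts with SPARQL
    graph patterns and rule-materialized defined classes, and compares
    ICV-normalized hippocampal volumes across cognitively stratified groups
    with one-way ANOVA and Fisher's LSD post-hoc tests. Includes a
    deterministic two-source synthetic cohort generator so the full pipeline
    is testable without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
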