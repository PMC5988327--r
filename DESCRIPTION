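Package: gsmtrace
Title: Traceable Reconstruction Workspace for Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A provenance-tracked store for genome-scale metabolic models
    (GSMs) together with the topological analyses used during a la carte
    reconstruction: network-expansion scope computation from seed compounds,
    detection of unproducible targets, enumeration of unblocking compounds,
    production-path extraction, and minimal topological gap-filling against a
    reaction database (including class/instance reaction instantiation over a
    compound ontology). Models can be merged from heterogeneous sources
    (annotation, orthology, gap-filling, manual curation) with per-entity
    source tags, read and written as SBML Level 2/3 or a flat attribute-based
    text dialect, mapped between identifier namespaces, and exported as
    stoichiometric matrices, RDF Turtle, pathway-completeness and provenance
    reports, or a static hyperlinked wiki. A configuration-driven pipeline
    runner makes whole reconstructions replayable, and tabular curation forms
    make manual edits diffable and replayable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
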