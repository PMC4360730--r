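Package: ontoFacets
Title: Multi-Ontology Slimming, Search and Metadata Validation for
    Genomics Experiment Records
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for managing genomics experiment metadata with
    biomedical ontologies, modeled on the curation machinery of large
    data coordination centers. Parses OBO flat files, merges anatomy,
    cell-type, experimental-factor, assay and chemical ontologies into
    one typed-relation directed acyclic graph, computes transitive
    ancestor closures and composed (inferred) relationships over is_a,
    part_of and derives_from edges, maps annotated terms onto named slim
    sets to build search facets, provides synonym-expanded free-text
    term search, and validates experiment records against ontology-driven
    integrity rules (term existence, obsolescence, biosample-type to
    ontology routing, and slim-conditional required fields such as the
    antibody requirement for immunoprecipitation assays).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
biocViews: Annotation, DataImport, Infrastructure, MetadataManagement
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
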