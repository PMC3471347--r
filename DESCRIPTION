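Package: semcube
Title: Multidimensional Semantic Spaces over Annotated Document Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds browsable multidimensional semantic spaces from text
    collections annotated against a concept taxonomy. Taxonomic subsumption
    is answered through an interval index; the taxonomy is partitioned into
    disjoint dimensions stratified into OLAP-safe antichain levels; documents
    are annotated by ranked dictionary lookup against a background language
    model, reduced to multidimensional facts through a graph-regularization
    framework with iterative word-sense disambiguation, and mined for
    semantic bridges (scored concept-pair associations) via contingency
    cubes. Includes a seeded synthetic-data generator with planted mentions
    and planted associations for end-to-end evaluation, plus readers and
    writers for the flat ontology, background, corpus and inline-XML
    annotation formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
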