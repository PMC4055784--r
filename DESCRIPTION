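Package: phytonet
Title: Phytochemical-Protein Interaction Networks for Diet-Disease Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A systems chemical biology toolkit linking the small-molecule
    constituents of plants to a candidate disease protein space. Aggregates
    ChEMBL-style bioactivity evidence into compound-protein interaction calls
    (pChEMBL/inhibition/potency thresholds, frequency-based interaction
    probability), matches compounds by InChIKey and Tanimoto fingerprint
    similarity, assembles a candidate target space from seed proteins and
    first-degree interaction neighbors, scores plant efficacy against the
    targeted protein union, builds a phi-coefficient protein co-targeting
    network with chi-square significance and Bonferroni correction, embeds
    compound descriptor space by classical multidimensional scaling, and
    counts substrate-side perturbations of a tissue metabolic network. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
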