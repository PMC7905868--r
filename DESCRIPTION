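Package: rdmap
Title: Semantic Distance Maps and Phenotype-Driven Search for Rare Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pairwise distances among rare diseases from phenotype-ontology
    (HPO-like) and gene-ontology (GO) semantics using normalized shortest
    common-ancestor-path distances, embeds diseases as a navigable 2-D map by
    classical multidimensional scaling with bootstrap-stability-selected k-means
    clusters, and ranks candidate diseases for sets of (possibly imprecise) query
    phenotypes. Includes loaders for OBO ontologies and Orphanet-style disease
    annotations, an in silico imprecise-phenotype benchmark, a literature-case
    ranking harness, and synthetic-fixture generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
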