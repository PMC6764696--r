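Package: sector5
Title: Five-Sector Resource-Allocation Partition of Genome-Wide Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a genome into five resource-allocation sectors
    (repressed, negative, invariant, positive, activated) from growth-rate
    series of expression or promoter-activity data, using per-nutrient
    singular value decompositions whose first two loadings capture baseline
    fractional expression and its monotone response to growth.  Downstream
    analyses integrate a directed transcription-factor network (regulators
    per sector, regulatory coherence against permutation nulls, TF-sector
    enrichment, vertex-sort hierarchy) and epigenetic data (promoter feature
    enrichment, chromatin-modifier effect strength and signed-effect
    classification, slow-growth-signature removal).  A synthetic-data
    generator with planted ground truth makes every stage verifiable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
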