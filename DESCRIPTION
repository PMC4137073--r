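Package: epgdbkit
Title: Toolkit for Pathway Predictions from Environmental Pathway/Genome Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of metabolic pathway predictions made from
    environmental (community) sequence data. Implements a weighted taxonomic
    distance (WTD) between the observed lowest-common-ancestor taxonomy of a
    pathway's coding sequences and the pathway's curated expected taxonomic
    range, with quartile-based taxonomic-disagreement classes; quality control
    and ORF-count normalization of long-form pathway tables; multi-sample and
    DNA/RNA presence-absence set analyses; detection of distributed metabolic
    pathways shared across genomes with a reaction-coverage plausibility
    filter; confusion-table performance metrics against gold-standard pathway
    sets; and seedable synthetic community generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
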