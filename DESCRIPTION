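Package: rabnet
Title: Resilience-Guided Analysis of Protein Interaction Networks for
    Metastasis Marker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the resilience of protein-protein
    interaction networks under random node failure using a modified
    Shannon diversity index of component sizes, for selecting an
    optimally sized network from an expansion series, and for
    prioritizing candidate genes around a seed (e.g. EMT) gene set via an
    adapted MaxLink workflow: immediate-neighbour extraction, Disease
    Ontology annotation filtering, and a loess confidence-band
    connectivity filter. Includes topology summaries with kneedle elbow
    hub detection and power-law exponent fitting, TNM-stratified
    differential-expression hit calling on FPKM cohorts, a seeded
    synthetic-data generator producing every input the pipeline
    consumes, and a small command-line interface.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
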