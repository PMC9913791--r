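Package: dacpdx
Title: Decitabine Response Analysis for T-LBL Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative epigenomics pipeline for pre-clinical studies of
    hypomethylating agents in T-cell lymphoblastic lymphoma patient-derived
    xenograft (PDX) models. Provides CpG-island methylator phenotype (CIMP)
    classification, the EpiTOC epigenetic mitotic clock, delta-beta
    differential methylation calling, negative-binomial differential
    expression with Benjamini-Hochberg adjustment, preranked gene-set
    enrichment, gene-level methylation-by-expression integration,
    consensus Hi-C A/B compartment assignment with an open-chromatin
    relative-risk statistic, bead-corrected leukemic-burden readouts, and
    survival comparison. A seeded synthetic-cohort generator emulates the
    statistical structure of a PDX vehicle/decitabine trial so that every
    stage of the pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
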