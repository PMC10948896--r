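Package: lipidcheck
Title: Lipidome Coregulation Networks and Cell-Cycle Phenotype Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking lipidome remodeling to transcriptome
    and cell-cycle phenotypes. Parses lipid species nomenclature, normalizes
    abundance tables by total signal and computes log2 fold-changes against
    time-matched vehicle controls, builds thresholded lipid coregulation
    networks with leave-one-out edge robustness, clusters fold-change
    profiles and tests groups for category enrichment with a two-sided
    Fisher's exact test, correlates lipids with differentially expressed
    genes and phenotype vectors, and quantifies cell-cycle state from
    microscopy by quantitative image-based cytometry (nuclear segmentation,
    ring sampling, CDK-activity ratios, DNA-content gating) and from
    kinase-translocation-reporter traces. A synthetic-data module generates
    all inputs with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
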