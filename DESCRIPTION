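Package: pertsyn
Title: Drug-Synergy and Pathway-Perturbation Analysis for Combination
    Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for establishing drug-combination synergy
    and dissecting its transcriptional mechanism. Implements Chou-Talalay
    median-effect analysis of dose-response data (combination index, dose
    reduction index, potentiation factor, Fa-CI curves), SAM-style
    permutation detection of differentially expressed genes with fudge
    factor and delta-controlled FDR, topology-based signaling pathway
    impact analysis (pNDE, pPERT, pG, pGFdr), fusion of significant
    pathways with extraction of the module spanned by directed shortest
    paths between differentially expressed genes, multigroup structural
    equation path modelling with likelihood-ratio and per-edge
    perturbation tests, and Kruskal-Wallis/Dunn comparison of methylation
    beta-values. A synthetic-data generator with planted ground truth
    makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
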