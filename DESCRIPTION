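Package: quiescentome
Title: Differential Expression, Enrichment, Regulator Networks and
    Cell-Cell Interaction Propensity for Macrophage Transcriptomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for bulk transcriptome
    analysis of treated macrophages under a paired 2x2 design
    (lactoferrin exposure crossed with LPS stimulation across shared
    donors). Implements per-gene linear modelling with empirical-Bayes
    variance moderation and moderated t-statistics, Benjamini-Hochberg
    multiple-testing adjustment, pathway over-representation analysis
    against expression-matched backgrounds, cross-contrast biological
    theme comparison, co-expression regulator-target network inference
    with scale-free soft thresholding, a composite regulator importance
    score, regulator-to-pathway attribution, and a bilinear cell-cell
    interaction propensity metric over curated physical and cytokine
    to receptor interaction channels. A synthetic-data module generates
    expression matrices, annotations, gene sets, interaction networks
    and reference immune-cell profiles with planted ground truth so
    every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
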