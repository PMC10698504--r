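Package: gemscreen
Title: Scoring Genome-Scale Metabolic Model Essentiality Predictions
    Against Mutant Fitness Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates gene-essentiality predictions from genome-scale
    metabolic models (GEMs) against pooled transposon-mutant fitness assays.
    Implements flux balance analysis (FBA) and parsimonious FBA on
    constraint-based models, Boolean gene-protein-reaction knockout
    propagation, growth-environment construction with vitamin/cofactor
    supplementation and reaction-level corrections, fitness-thresholded
    precision-recall evaluation with null-model padding, carbon-source-to-gene
    distances on the bipartite metabolite-reaction graph, gradient-boosted
    classification of mispredicted growth phenotypes from simulated flux
    profiles with Shapley attribution, and a synthetic toy-model generator
    with known ground-truth conditional essentiality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    xml2,
    igraph,
    xgboost,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
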