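Package: epistab
Title: Sex-Stratified Case-Control Association, MB-MDR Interaction
    Analysis and Model Stability Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sex-stratified case-control analysis of candidate-gene
    panels: Hardy-Weinberg exact tests, single-variant association under
    dominant/recessive/additive models with crude and Woolf-interval odds
    ratios and (adaptive) permutation p-values, EM haplotype frequency
    estimation with pairwise linkage disequilibrium, pairwise
    genotype-combination (diplotype) scans with Haldane-Anscombe continuity
    correction and FDR control, a Model-Based Multifactor Dimensionality
    Reduction (MB-MDR) engine for gene-gene and gene-environment interactions
    of orders 2-4 with covariate adjustment and permutation testing, and a
    model stability-and-prioritization algorithm combining permutation
    confidence-interval filtering, per-order FDR, factor recurrence and a
    weighted composite score. Includes closed-form and Monte-Carlo power
    calculations, a synthetic cohort generator with planted sex-specific
    interaction effects, and a nine-stage pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
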