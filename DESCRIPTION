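Package: flscape
Title: Cytokine-Response Signatures, Motif Deviations and Spatial Topics
    for Fibroblast Activation States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@flscape.org",
           role = c("aut", "cre"))
Description: Attributes fibroblast (fibroblast-like synoviocyte) activation
    states to cytokine exposures. Derives directed cytokine-response gene
    signatures from bulk stimulation experiments with a negative-binomial
    Wald test (median-of-ratios size factors, trended dispersion shrinkage,
    optional ridge-shrunken fold changes); scores signatures on single cells
    and spatial spots with bin-matched control genes; runs hurdle-model
    single-cell differential expression with a detection-rate covariate and
    preranked gene-set enrichment analysis; computes chromVAR-style
    transcription-factor motif accessibility deviations against GC- and
    accessibility-matched background peaks with expression gating and
    per-state Wilcoxon ranking; fits latent Dirichlet allocation topic
    models to spatial transcriptomics by collapsed Gibbs sampling with
    Bayes-factor model selection and Poisson Kullback-Leibler marker genes;
    and quantifies spot-level colocalization and hex-neighborhood dampening.
    Includes seed-deterministic synthetic generators for all four input data
    kinds with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
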