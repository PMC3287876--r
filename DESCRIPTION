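Package: bfscreen
Title: Bayesian Factor Screening for Quantitative-Trait Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens SNP variants or genes for association with a quantitative
    trait by Bayesian model selection over a restricted model space. All linear
    models with a fixed number of active factors are compared through a
    closed-form conjugate marginal likelihood, computed by an augmented-QR
    regression, and the model space is explored with a Metropolis-Hastings
    sampler whose visit counts estimate marginal posterior inclusion
    probabilities. Supports SNP-level and gene-level (grouped-variant)
    screening, a BIC-style size-penalized model prior for gene models, a
    synthetic mini-exome data generator with known causal truth, and
    reporting utilities (top-k membership across replicates, posterior
    threshold tables, realized false-positive discovery rates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
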