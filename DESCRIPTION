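Package: fmtstrains
Title: Strain-Level Tracking of Donor Microbiota Engraftment After Fecal
    Microbiota Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify strain-level engraftment of donor microbiota in
    recipients of fecal microbiota transplantation (FMT) from marker-gene
    alignment data. Builds per-species single-nucleotide-variant (SNV) profiles
    from nucleotide count tables, calls shared strains between samples by
    maximum variant profile similarity (MVS), attributes every post-FMT strain
    to donor, recipient, coexisting or new origins, computes compositional
    community metrics (Shannon diversity, centered log-ratio transforms,
    Aitchison distances, dysbiosis scores, lifestyle burdens), and fits
    binomial-logit mixed-effects models of donor strain engraftment at the
    case and the individual-strain level, including marginal-effect,
    abundance-substitution and donor-swap simulations. A fully seeded
    synthetic FMT cohort generator with known ground truth (strain genotypes,
    planted transfer, persistence and coexistence events, and a generative
    logistic engraftment model) supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
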