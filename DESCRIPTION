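Package: betalactamdiv
Title: Beta-Lactam Exposure and Longitudinal Airway Microbiome Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links beta-lactam pharmacokinetic/pharmacodynamic exposure to
    longitudinal changes in cystic fibrosis airway microbiome diversity.
    Simulates one-compartment intermittent-infusion concentration profiles,
    computes the fraction of the dosing interval above the minimum inhibitory
    concentration (fT>MIC) with class-specific pharmacodynamic targets, and
    classifies antibiotic courses as therapeutic or subtherapeutic. Provides
    rarefaction and Hill-number alpha diversity (richness, Chao, ACE, Shannon,
    inverse Simpson), Bray-Curtis/Jaccard/Morisita-Horn dissimilarities with
    principal coordinates analysis and permutation PERMANOVA, paired
    encounter-delta construction with exchangeable-correlation generalized
    estimating equations and robust (sandwich) variance, a permutation
    differential-abundance test with Benjamini-Hochberg adjustment, and a
    Dirichlet-multinomial synthetic-cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
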