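Package: macaqueIT
Title: Pedigree-Based Quantitative Genetics of Infant Inhibited Temperament
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for infant inhibited temperament (IT) in
    rhesus macaques: scoring of Activity and Emotionality factors from
    BioBehavioral Assessment items and the dichotomous IT classification;
    logistic-regression and chi-squared analyses of longitudinal treat
    refusal; pedigree-based heritability and genetic correlation by animal
    model REML; kinship-adjusted single-variant mixed-model association;
    and a permutation gene-set enrichment test on per-gene minimum
    association p-values.  Includes a synthetic-data generator (pedigree
    simulation, gene-dropping of biallelic variants, bivariate
    additive-genetic phenotypes, treat-refusal outcomes) so that every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
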