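Package: BiallelicBurden
Title: Recessive Inheritance and Gene-Burden Analysis of Rare Deleterious Variants
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects recessive (homozygous and compound-heterozygous) inheritance
    of rare and low-frequency deleterious variants in a gene and quantifies
    disease risk under additive, genotypic, and recessive genetic models.
    Provides pedigree- and population-based phasing of candidate compound
    heterozygotes (including a two-locus haplotype-frequency EM), predicted
    loss-of-function and deleterious-missense variant classification with
    minor-allele-frequency filters, Fisher-exact and score-test odds ratios
    with Woolf confidence intervals, Firth penalized logistic gene-burden
    regression, ICD-code electronic-health-record case definitions with
    onset-age and diagnosis lead-time summaries, a phenome-wide association
    scan, and a synthetic trio/singleton cohort generator with genotype-
    dependent penetrance for end-to-end testing without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
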