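Package: polygreml
Title: Genomic REML, Polygenic Scores and LD Score Regression for
    Cross-Trait Genetic Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the shared genetic architecture of a
    case-control disease trait and a quantitative reproductive trait
    measured in independent cohorts. Implements PLINK-1 binary genotype
    input/output with cross-cohort allele alignment, the standard
    genotype and sample quality-control filters (call rate, minor allele
    frequency, exact Hardy-Weinberg tests, ancestry outliers, relatedness
    pruning), genomic relationship matrices with principal components,
    single- and multi-trait average-information REML with genomic BLUP
    prediction, profile polygenic risk scores, a quadratic
    response-transform regression for U-shaped risk relationships, LD
    score estimation and LD score regression with block-jackknife
    standard errors, and a liability-threshold simulator for generating
    matched synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
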