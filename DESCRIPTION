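Package: mdrkit
Title: Multifactor Dimensionality Reduction for Case-Control Epistasis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control single-nucleotide polymorphism (SNP) analysis with an
    emphasis on gene-gene interaction (epistasis) detection by multifactor
    dimensionality reduction (MDR). Provides genotype/allele frequency tables
    and Hardy-Weinberg equilibrium testing, Fisher exact and covariate-adjusted
    codominant logistic-regression association tests, the MDR combination
    search with stratified cross-validation, balanced accuracy,
    cross-validation consistency and permutation significance, entropy-based
    interaction-information maps, and a penetrance-model simulator of
    case-control genotype data for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
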