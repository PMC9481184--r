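Package: sexfst
Title: Life-Cycle Between-Sex FST Metrics for Sex-Differential Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects polygenic signals of sex-differential and sexually
    antagonistic selection from diploid genotypes and lifetime reproductive
    success (LRS) phenotypes. Implements per-site adult, reproductive, gametic
    and unfolded between-sex FST metrics with their theoretical (chi-square and
    product-normal) and permutation null distributions, artefact-aware site
    quality control (excess-heterozygosity, minor-homozygote-deficit and
    sex-differential-missingness tests with Benjamini-Hochberg control),
    structure-corrected analogues based on principal-component-adjusted
    regression GWAS, modes-of-evolution association tests, and a forward
    cohort simulator with known sex-specific viability and reproductive
    selection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
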