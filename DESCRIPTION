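Package: admixprs
Title: Ancestry-Aware Polygenic Risk Score Analysis for Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unweighted polygenic risk score (PRS) analysis in
    admixed populations: effect-allele dosage extraction from VCF, windowed
    pairwise-r2 linkage-disequilibrium pruning, regression of PRS on
    continental ancestry fractions, permutation null distributions for
    between-population PRS differences, and a derived-allele-frequency
    (DAF) matched resampling control that yields an ancestry-corrected
    delta-PRS z-score. Includes a synthetic admixed-cohort generator
    (Dirichlet admixture proportions over Balding-Nichols population
    allele frequencies, with explicit ancestral/derived polarization and
    an embeddable risk architecture) so the full pipeline can be exercised
    and calibrated without access to genotype databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
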