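Package: riskspectra
Title: Allelic Spectra of Disease Risk Alleles Under Negative Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how negative selection shapes the allele-frequency
    spectra of GWAS-reported disease risk alleles. Computes a literature-derived
    environment/lifestyle index (ELI) per disease, minor-risk-allele (MiRA)
    proportions with binomial standard errors, five-bin risk-allele frequency
    spectra against a frequency-independence null, and overlap between
    genotyping-platform SNP manifests and SNPs flagged for recent positive
    selection. Includes first-principles Spearman, chi-square and one-way ANOVA
    routines, a forward Wright-Fisher simulator of the recently-neutral,
    currently-deleterious risk-allele model, and a synthetic-data generator for
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
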