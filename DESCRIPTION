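Package: apoepaf
Title: Population Attributable Fractions for APOE Genotypes and GWAS Loci
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the proportion of Alzheimer's disease,
    all-cause dementia and cerebral amyloidosis attributable to carriage of
    the APOE epsilon-3 and epsilon-4 alleles. Codes APOE epsilon genotypes
    from rs429358/rs7412 diplotypes, tests Hardy-Weinberg equilibrium,
    estimates per-genotype relative risks against an epsilon-2/epsilon-2
    reference (crude contingency estimates, log-binomial and logistic
    regression, odds-ratio re-orientation and odds-ratio-to-risk-ratio
    conversion), computes multi-level population attributable fractions with
    plug-in confidence intervals, partitions the total fraction between the
    epsilon-3 and epsilon-4 alleles, ranks attributable fractions for
    arbitrary biallelic GWAS loci, and simulates individual-level cohorts
    and case-control samples with known genotype-specific risks so every
    stage of the pipeline can be validated against a closed-form truth.
    Bundles published APOE genotype count tables and relative-risk
    estimates from the ADGC, UK Biobank, FinnGen and A4 samples as fixtures,
    with end-to-end reproduction recipes for the ADGC and A4 analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
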