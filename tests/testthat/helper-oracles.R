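# Independent oracles used across the suite. These never call the package
# functions whose output they check.

# Brute-force excess-case attributable fraction: of the observed cases, the
# number that would still have occurred if every stratum carried the
# reference risk is sum(a_i / RR_i); the attributable fraction is the excess
# over the observed total.
oracle_excess_case_paf <- function(case_counts, rr) {
  stopifnot(identical(names(case_counts), names(rr)))
  observed <- sum(case_counts)
  counterfactual <- sum(case_counts / rr)
  (observed - counterfactual) / observed
}

# Levin's two-level prevalence-based formula.
oracle_levin <- function(prevalence, rr) {
  prevalence * (rr - 1) / (1 + prevalence * (rr - 1))
}

# Three-stratum enumeration for a biallelic locus: stratum risks are built
# from the reference odds and the genotype odds ratios directly (never via
# the package's conversion), and the attributable fraction is the excess
# case count in a fixed population.
oracle_locus_enumeration <- function(eaf, or, p0,
                                     model = c("multiplicative", "dominant"),
                                     n = 1e7) {
  model <- match.arg(model)
  q <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
  or_g <- if (model == "multiplicative") c(1, or, or^2) else c(1, or, or)
  odds0 <- p0 / (1 - p0)
  risk <- (odds0 * or_g) / (1 + odds0 * or_g)
  cases <- n * q * risk
  baseline_cases <- n * q * p0
  (sum(cases) - sum(baseline_cases)) / sum(cases)
}

# Direct chi-square arithmetic for triallelic Hardy-Weinberg counts.
oracle_hwe_chisq <- function(counts) {
  n <- sum(counts)
  f2 <- (2 * counts[["e2/e2"]] + counts[["e2/e3"]] + counts[["e2/e4"]]) / (2 * n)
  f3 <- (2 * counts[["e3/e3"]] + counts[["e2/e3"]] + counts[["e3/e4"]]) / (2 * n)
  f4 <- (2 * counts[["e4/e4"]] + counts[["e2/e4"]] + counts[["e3/e4"]]) / (2 * n)
  e <- n * c(f2^2, 2 * f2 * f3, f3^2, 2 * f2 * f4, 2 * f3 * f4, f4^2)
  o <- unname(counts[c("e2/e2", "e2/e3", "e3/e3", "e2/e4", "e3/e4", "e4/e4")])
  sum((o - e)^2 / e)
}

# Published-value fixtures used by several files.
adgc_case_counts <- function() {
  c("e2/e2" = 5, "e2/e3" = 113, "e3/e3" = 1273, "e2/e4" = 107,
    "e3/e4" = 1897, "e4/e4" = 623)
}
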