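#' APOE genotype levels
#'
#' The six unordered pairs of the common APOE epsilon alleles, in the
#' conventional order from lowest to highest Alzheimer's disease risk.
#' `"e2/e2"` is the designated reference level for all relative-risk and
#' attributable-fraction computations in this package, because attributable
#' fractions require the lowest-risk exposure level as reference.
#'
#' @return Character vector of the six genotype labels.
#' @export
apoe_genotypes <- function() {
  c("e2/e2", "e2/e3", "e3/e3", "e2/e4", "e3/e4", "e4/e4")
}

#' The five risk-increasing APOE genotypes
#'
#' All genotype levels except the `"e2/e2"` reference.
#'
#' @return Character vector of five genotype labels.
#' @export
apoe_risk_genotypes <- function() {
  setdiff(apoe_genotypes(), "e2/e2")
}

# Canonicalise an unphased diplotype string ("CT", "T/C", "tc") to a sorted
# two-letter key, validating against the SNP's allele set.
normalize_diplotype <- function(x, alleles, snp) {
  x <- toupper(gsub("[/| ]", "", as.character(x)))
  bad <- !is.na(x) & nchar(x) != 2L
  if (any(bad)) {
    stop("diplotype at ", snp, " must contain exactly two alleles: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  a1 <- substr(x, 1L, 1L)
  a2 <- substr(x, 2L, 2L)
  ok <- is.na(x) | (a1 %in% alleles & a2 %in% alleles)
  if (!all(ok)) {
    stop("invalid allele symbol at ", snp, " (expected ",
         paste(alleles, collapse = "/"), "): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}

#' Code APOE epsilon genotypes from rs429358 and rs7412 diplotypes
#'
#' Translates unphased diplotypes at the two APOE-defining SNPs into the six
#' epsilon genotypes, using the haplotype definitions
#' e2 = (rs429358-T, rs7412-T), e3 = (rs429358-T, rs7412-C) and
#' e4 = (rs429358-C, rs7412-C). The rare fourth haplotype (rs429358-C,
#' rs7412-T), historically called epsilon-1, is not assigned: diplotype
#' combinations that can only be explained by an e1-bearing haplotype pair
#' return `NA`.
#'
#' The double heterozygote (rs429358 C/T together with rs7412 C/T) is
#' genuinely ambiguous without phase: it is consistent with both e2/e4 and
#' e1/e3. Because e1 is vanishingly rare in all populations, the default
#' policy assigns e2/e4; set `ambiguity_policy = "missing"` to return `NA`
#' instead.
#'
#' @param rs429358 Character vector of diplotypes at rs429358, e.g. `"CT"`
#'   or `"T/T"`; allele order is not meaningful. Alleles must be T or C.
#' @param rs7412 Character vector of diplotypes at rs7412; alleles C or T.
#' @param ambiguity_policy How to resolve the double heterozygote:
#'   `"e2/e4"` (default) or `"missing"`.
#' @return Factor with levels [apoe_genotypes()]; `NA` where the diplotype
#'   implies an e1 haplotype (or for the ambiguous case under the
#'   `"missing"` policy).
#' @examples
#' code_apoe(c("TT", "CC", "CT"), c("CC", "CC", "CT"))
#' @export
code_apoe <- function(rs429358, rs7412,
                      ambiguity_policy = c("e2/e4", "missing")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (length(rs429358) != length(rs7412)) {
    stop("rs429358 and rs7412 must have the same length", call. = FALSE)
  }
  k1 <- normalize_diplotype(rs429358, c("T", "C"), "rs429358")
  k2 <- normalize_diplotype(rs7412, c("C", "T"), "rs7412")

  # keys are sorted, so heterozygotes are always "CT"
  map <- c(
    "TT.TT" = "e2/e2",
    "TT.CT" = "e2/e3",
    "TT.CC" = "e3/e3",
    "CT.CC" = "e3/e4",
    "CC.CC" = "e4/e4",
    "CT.CT" = if (ambiguity_policy == "e2/e4") "e2/e4" else NA_character_,
    "CC.CT" = NA_character_,  # e1/e4
    "CC.TT" = NA_character_,  # e1/e1
    "CT.TT" = NA_character_   # e1/e2
  )
  factor(unname(map[paste(k1, k2, sep = ".")]), levels = apoe_genotypes())
}

#' Emit the rs429358/rs7412 diplotype encoding a given APOE genotype
#'
#' The inverse of [code_apoe()]: for each genotype, the diplotype a
#' genotyping assay would observe. For e2/e4 this is the ambiguous double
#' heterozygote (C/T at both SNPs), so round-tripping through [code_apoe()]
#' exercises the ambiguity policy.
#'
#' @param genotype Character or factor vector of genotype labels.
#' @return A [tibble::tibble] with columns `rs429358` and `rs7412`.
#' @export
apoe_diplotype <- function(genotype) {
  genotype <- as.character(genotype)
  bad <- !is.na(genotype) & !genotype %in% apoe_genotypes()
  if (any(bad)) {
    stop("unknown genotype label(s): ",
         paste(unique(genotype[bad]), collapse = ", "), call. = FALSE)
  }
  d1 <- c("e2/e2" = "TT", "e2/e3" = "TT", "e3/e3" = "TT",
          "e2/e4" = "CT", "e3/e4" = "CT", "e4/e4" = "CC")
  d2 <- c("e2/e2" = "TT", "e2/e3" = "CT", "e3/e3" = "CC",
          "e2/e4" = "CT", "e3/e4" = "CC", "e4/e4" = "CC")
  tibble::tibble(rs429358 = unname(d1[genotype]),
                 rs7412 = unname(d2[genotype]))
}

#' Allele-carriage indicators for APOE genotypes
#'
#' Flags whether each of e2, e3 and e4 appears in a genotype. Carriage
#' groups overlap (an e2/e4 individual carries both e2 and e4), so carriage
#' counts tabulated over a sample sum to more than the sample size.
#'
#' @param genotype Character or factor vector of genotype labels.
#' @return Tibble with logical columns `carries_e2`, `carries_e3`,
#'   `carries_e4`.
#' @export
carriage_flags <- function(genotype) {
  genotype <- as.character(genotype)
  bad <- !is.na(genotype) & !genotype %in% apoe_genotypes()
  if (any(bad)) {
    stop("unknown genotype label(s): ",
         paste(unique(genotype[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    carries_e2 = grepl("e2", genotype),
    carries_e3 = grepl("e3", genotype),
    carries_e4 = grepl("e4", genotype)
  )
}

#' Triallelic Hardy-Weinberg equilibrium test for APOE genotype counts
#'
#' Estimates the e2/e3/e4 allele frequencies from six-genotype counts by
#' gene counting, forms the expected genotype counts under Hardy-Weinberg
#' proportions, and compares observed to expected with an asymptotic
#' chi-square statistic on 3 degrees of freedom (6 genotype classes minus 1
#' minus 2 free allele frequencies).
#'
#' @param counts Named numeric vector of genotype counts (names from
#'   [apoe_genotypes()]), or a count table from [genotype_counts()] in which
#'   case cases and controls/totals are pooled into one population.
#' @return List with `chi_square`, `df`, `p`, `allele_freqs` (named e2, e3,
#'   e4), `observed` and `expected` (named six-genotype vectors).
#' @examples
#' hwe_test(c("e2/e2" = 9, "e2/e3" = 42, "e3/e3" = 49,
#'            "e2/e4" = 42, "e3/e4" = 98, "e4/e4" = 49))
#' @export
hwe_test <- function(counts) {
  counts <- as_genotype_count_vector(counts)
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)

  f <- c(
    e2 = (2 * counts[["e2/e2"]] + counts[["e2/e3"]] + counts[["e2/e4"]]),
    e3 = (2 * counts[["e3/e3"]] + counts[["e2/e3"]] + counts[["e3/e4"]]),
    e4 = (2 * counts[["e4/e4"]] + counts[["e2/e4"]] + counts[["e3/e4"]])
  ) / (2 * n)

  expected <- n * c(
    "e2/e2" = f[["e2"]]^2,
    "e2/e3" = 2 * f[["e2"]] * f[["e3"]],
    "e3/e3" = f[["e3"]]^2,
    "e2/e4" = 2 * f[["e2"]] * f[["e4"]],
    "e3/e4" = 2 * f[["e3"]] * f[["e4"]],
    "e4/e4" = f[["e4"]]^2
  )

  keep <- expected > 0
  chi_square <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  df <- 3L
  list(
    chi_square = chi_square,
    df = df,
    p = stats::pchisq(chi_square, df = df, lower.tail = FALSE),
    allele_freqs = f,
    observed = counts,
    expected = expected
  )
}

# Coerce genotype counts (named vector or genotype_counts table) to a named
# six-genotype vector, pooling outcome columns for a table.
as_genotype_count_vector <- function(counts) {
  if (inherits(counts, "genotype_counts")) {
    other <- if (attr(counts, "design") == "case-control") {
      counts$controls
    } else {
      counts$totals - counts$cases
    }
    counts <- stats::setNames(counts$cases + other, counts$genotype)
  }
  if (is.null(names(counts)) || !all(apoe_genotypes() %in% names(counts))) {
    stop("counts must be named with all six APOE genotypes", call. = FALSE)
  }
  counts <- counts[apoe_genotypes()]
  if (any(counts < 0)) stop("genotype counts must be non-negative",
                            call. = FALSE)
  counts
}
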