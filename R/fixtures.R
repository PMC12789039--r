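#' Published APOE count tables and risk estimates bundled as fixtures
#'
#' The in-text datasets this package's reproduction recipes run on:
#' \describe{
#'   \item{adgc_counts}{Case-control genotype counts from the ADGC
#'     neuropathologically confirmed AD sample (4018 cases, 989 controls).}
#'   \item{a4_counts}{Two-level (e2/e2 vs e3/e4-carrier) amyloid-PET
#'     positivity counts from the A4 screening sample (4415 subjects, 1203
#'     amyloid-positive at SUVr >= 1.15).}
#'   \item{adgc_rrs, ukb_rrs, finngen_rrs, a4_rrs}{Published per-genotype
#'     risk ratios (with 95% CIs) against e2/e2 for each sample; the UKB
#'     estimates are log-binomial, the others converted from odds ratios.}
#'   \item{adgc_pafs, ukb_pafs, finngen_pafs, a4_pafs}{The published
#'     per-genotype attributable fractions (%, with 95% CIs) for each
#'     sample, usable as inputs to aggregation.}
#'   \item{suvr_threshold}{The amyloid-PET SUVr positivity cut-off, 1.15.}
#' }
#'
#' Cell totals are checked against the published sample sizes at every call,
#' so a corrupted fixture fails loudly rather than propagating.
#'
#' @return Named list of fixtures.
#' @examples
#' fx <- apoe_fixtures()
#' fx$adgc_counts
#' @export
apoe_fixtures <- function() {
  gt <- apoe_genotypes()

  adgc_counts <- genotype_counts(
    gt,
    cases = c(5, 113, 1273, 107, 1897, 623),
    controls = c(19, 147, 638, 20, 155, 10)
  )

  a4_counts <- genotype_counts(
    c("e2/e2", "carrier"),
    cases = c(1, 1202),
    totals = c(25, 4390)
  )

  rg <- apoe_risk_genotypes()
  rr_set <- function(est, lo, hi, provenance) {
    risk_estimates(rg, est, lo, hi, measure = "rr", reference = "e2/e2",
                   provenance = provenance)
  }
  adgc_rrs <- rr_set(c(2.94, 7.21, 17.23, 32.26, 70.81),
                     c(1.38, 2.73, 4.42, 12.48, 31.76),
                     c(5.71, 16.81, 46.83, 59.95, 92.23),
                     "published (converted from ORs, p0 = 0.01)")
  ukb_rrs <- rr_set(c(1.68, 2.19, 4.03, 8.39, 23.36),
                    c(0.69, 0.91, 1.64, 3.50, 9.71),
                    c(4.07, 5.25, 9.91, 20.13, 56.19),
                    "published (log-binomial)")
  finngen_rrs <- rr_set(c(1.63, 2.29, 4.44, 6.37, 9.79),
                        c(1.00, 1.40, 2.87, 4.32, 7.44),
                        c(2.63, 3.71, 6.79, 9.25, 12.73),
                        "published (converted from ORs)")
  a4_rrs <- rr_set(c(3.30, 4.27, 8.36, 12.39, 20.32),
                   c(0.48, 0.64, 1.42, 2.80, 8.67),
                   c(13.21, 14.88, 19.58, 21.89, 24.24),
                   "published (converted from ORs)")

  paf_tbl <- function(paf, lo, hi) {
    tibble::tibble(genotype = rg, paf = paf, lower = lo, upper = hi)
  }
  adgc_pafs <- paf_tbl(c(1.9, 27.3, 2.5, 45.7, 15.3),
                       c(0.8, 20.1, 2.1, 43.4, 15.0),
                       c(2.3, 29.8, 2.6, 46.4, 15.3))
  ukb_pafs <- paf_tbl(c(2.0, 17.0, 1.8, 41.9, 12.9),
                      c(-2.2, -3.1, 0.9, 34.0, 12.1),
                      c(3.8, 25.4, 2.2, 45.2, 13.2))
  finngen_pafs <- paf_tbl(c(1.6, 22.7, 1.9, 35.6, 9.7),
                          c(0.0, 11.5, 1.6, 32.5, 9.4),
                          c(2.6, 29.4, 2.1, 37.7, 10.0))
  a4_pafs <- paf_tbl(c(3.5, 25.9, 2.7, 44.9, 8.2),
                     c(-5.1, -16.5, 1.0, 32.0, 7.7),
                     c(4.6, 31.5, 2.9, 46.6, 8.3))

  fx <- list(adgc_counts = adgc_counts, a4_counts = a4_counts,
             adgc_rrs = adgc_rrs, ukb_rrs = ukb_rrs,
             finngen_rrs = finngen_rrs, a4_rrs = a4_rrs,
             adgc_pafs = adgc_pafs, ukb_pafs = ukb_pafs,
             finngen_pafs = finngen_pafs, a4_pafs = a4_pafs,
             suvr_threshold = 1.15)
  check_fixture_integrity(fx)
  fx
}

# Totals must match the published sample sizes exactly.
check_fixture_integrity <- function(fx) {
  ok <- sum(fx$adgc_counts$cases) == 4018 &&
    sum(fx$adgc_counts$controls) == 989 &&
    sum(fx$a4_counts$totals) == 4415 &&
    sum(fx$a4_counts$cases) == 1203 &&
    identical(fx$suvr_threshold, 1.15)
  if (!ok) {
    stop("fixture integrity check failed: embedded counts do not match ",
         "the published sample totals", call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate published per-genotype attributable fractions
#'
#' Sums per-genotype attributable-fraction point estimates (and their
#' plug-in confidence bounds) into a total, the aggregation used for cohorts
#' where only the per-genotype fractions are available.
#'
#' @param pafs Tibble with columns `paf` and optionally `lower`, `upper`
#'   (e.g. one of the `*_pafs` fixtures, in %).
#' @return Named vector `c(total, lower, upper)` on the same scale as the
#'   input.
#' @export
aggregate_pafs <- function(pafs) {
  stopifnot("paf" %in% names(pafs))
  c(total = sum(pafs$paf),
    lower = if ("lower" %in% names(pafs)) sum(pafs$lower) else NA_real_,
    upper = if ("upper" %in% names(pafs)) sum(pafs$upper) else NA_real_)
}
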