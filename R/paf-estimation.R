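#' Attributable fraction contributed by one exposure level
#'
#' The multi-level population attributable fraction assigns each exposure
#' level the contribution \eqn{PAF_i = p_{ci} (RR_i - 1) / RR_i}, where
#' \eqn{p_{ci}} is the fraction of all cases falling in level i and
#' \eqn{RR_i} its risk ratio against the lowest-risk reference. Summing over
#' the non-reference levels gives the total fraction of cases that would not
#' occur if every level carried the reference risk.
#'
#' @param p_ci Case fraction(s) in \[0, 1\]; vectorised with `rr`.
#' @param rr Positive risk ratio(s) against the reference.
#' @return Per-level attributable fraction(s), as proportions.
#' @examples
#' genotype_paf(623 / 4018, 70.81)
#' @export
genotype_paf <- function(p_ci, rr) {
  if (any(p_ci < 0 | p_ci > 1, na.rm = TRUE)) {
    stop("case fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(rr <= 0, na.rm = TRUE)) {
    stop("risk ratios must be positive", call. = FALSE)
  }
  p_ci * (rr - 1) / rr
}

#' Case fractions from a count table
#'
#' Fraction of all cases in each exposure level, \eqn{p_{ci} = a_i / \sum a}.
#'
#' @param counts A [genotype_counts()] table (either design).
#' @return Named numeric vector of case fractions summing to one.
#' @export
case_fractions <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  total <- sum(counts$cases)
  if (total <= 0) stop("no cases in the count table", call. = FALSE)
  stats::setNames(counts$cases / total, counts$genotype)
}

#' Multi-level population attributable fraction with plug-in intervals
#'
#' Combines case fractions with per-level risk ratios into per-level and
#' total attributable fractions. The reference level contributes zero by
#' construction. Confidence bounds are obtained by re-evaluating every
#' per-level fraction at the lower (respectively upper) confidence limits of
#' the risk ratios and summing — a plug-in interval that propagates only the
#' RR uncertainty and ignores sampling error in the case fractions, which
#' makes it anti-conservative.
#'
#' @param fractions Named case-fraction vector (from [case_fractions()]), or
#'   a [genotype_counts()] table from which case fractions are taken. Levels
#'   must cover every level of `estimates`; a fraction for the reference
#'   level is allowed and ignored in the sum.
#' @param estimates A `risk_estimates` set with measure `"rr"`.
#' @return A tibble of class `paf_table` with columns `genotype`,
#'   `case_fraction`, `rr`, `paf`, `paf_lower`, `paf_upper`, and attributes
#'   `total`, `total_lower`, `total_upper`, `reference`, `p0` (when the RRs
#'   came from an OR conversion) and `provenance`.
#' @examples
#' fx <- apoe_fixtures()
#' total_paf(fx$adgc_counts, fx$adgc_rrs)
#' @export
total_paf <- function(fractions, estimates) {
  stopifnot(inherits(estimates, "risk_estimates"))
  if (attr(estimates, "measure") != "rr") {
    stop("total_paf() needs risk ratios; convert odds ratios first with ",
         "convert_or_set()", call. = FALSE)
  }
  if (inherits(fractions, "genotype_counts")) {
    fractions <- case_fractions(fractions)
  }
  missing_lv <- setdiff(estimates$genotype, names(fractions))
  if (length(missing_lv)) {
    stop("no case fraction for level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  p_ci <- unname(fractions[estimates$genotype])
  df <- tibble::tibble(
    genotype = estimates$genotype,
    case_fraction = p_ci,
    rr = estimates$estimate,
    paf = genotype_paf(p_ci, estimates$estimate),
    paf_lower = genotype_paf(p_ci, estimates$lower),
    paf_upper = genotype_paf(p_ci, estimates$upper)
  )
  structure(df,
            total = sum(df$paf),
            total_lower = sum(df$paf_lower),
            total_upper = sum(df$paf_upper),
            reference = attr(estimates, "reference"),
            p0 = attr(estimates, "p0"),
            provenance = attr(estimates, "provenance"),
            class = c("paf_table", class(df)))
}

#' Total attributable fraction (and bounds) from a `paf_table`
#'
#' @param x A `paf_table` from [total_paf()] or [true_paf()].
#' @return Named numeric vector `c(total, lower, upper)`, as proportions.
#' @export
paf_total <- function(x) {
  stopifnot(inherits(x, "paf_table"))
  c(total = attr(x, "total"),
    lower = attr(x, "total_lower"),
    upper = attr(x, "total_upper"))
}

#' @export
print.paf_table <- function(x, ...) {
  fmt <- function(p, lo, hi) {
    sprintf("%.1f (%.1f, %.1f)", 100 * p, 100 * lo, 100 * hi)
  }
  cat("Population attributable fractions vs ", attr(x, "reference"),
      " [", attr(x, "provenance"), "]\n", sep = "")
  out <- data.frame(
    genotype = x$genotype,
    `RR` = sprintf("%.2f", x$rr),
    `PAF (95% CI), %` = fmt(x$paf, x$paf_lower, x$paf_upper),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  tot <- paf_total(x)
  cat("Total:", fmt(tot[1], tot[2], tot[3]), "\n")
  invisible(x)
}

#' Partition the APOE attributable fraction between the e3 and e4 alleles
#'
#' The genotype-level fractions assign e2/e3 and e3/e3 unambiguously to e3,
#' and e2/e4 and e4/e4 to e4; the mixed e3/e4 genotype's contribution must
#' be split by a rule. Under the default `"rr-proportional"` rule the e4
#' share of the e3/e4 fraction is \eqn{RR(e2/e4) / (RR(e2/e3) + RR(e2/e4))}
#' — the relative single-copy risk of each allele on an e2 background — and
#' the e3 share is its complement. The `"excess-rr-proportional"` rule
#' weights by \eqn{RR - 1} instead. Either way the two allele shares sum
#' exactly to the five-genotype total.
#'
#' Confidence bounds are plug-in: the partition is re-evaluated with every
#' per-genotype fraction and split weight taken at the lower (respectively
#' upper) RR confidence limits. Like the total-PAF interval this propagates
#' only RR uncertainty.
#'
#' @param paf A six-genotype `paf_table` referenced on e2/e2.
#' @param estimates The `risk_estimates` set (measure `"rr"`) the table was
#'   built from; needed for the e2/e3 and e2/e4 split weights.
#' @param rule `"rr-proportional"` (default) or `"excess-rr-proportional"`.
#' @return Tibble of class `allele_partition` with one row per allele
#'   (`paf`, `paf_lower`, `paf_upper`) and attributes `rule` and
#'   `share_e4` (the point-estimate e4 share of the e3/e4 fraction).
#' @export
partition_alleles <- function(paf, estimates,
                              rule = c("rr-proportional",
                                       "excess-rr-proportional")) {
  rule <- match.arg(rule)
  stopifnot(inherits(paf, "paf_table"), inherits(estimates, "risk_estimates"))
  needed <- apoe_risk_genotypes()
  if (!all(needed %in% paf$genotype) || attr(paf, "reference") != "e2/e2") {
    stop("allele partition needs the five risk genotypes referenced on e2/e2",
         call. = FALSE)
  }
  rr_of <- function(col) {
    stats::setNames(estimates[[col]], estimates$genotype)[needed]
  }
  paf_of <- function(col) {
    stats::setNames(paf[[col]], paf$genotype)[needed]
  }
  weight <- function(rr) {
    w <- switch(rule,
                "rr-proportional" = rr,
                "excess-rr-proportional" = rr - 1)
    w[["e2/e4"]] / (w[["e2/e3"]] + w[["e2/e4"]])
  }
  split_once <- function(pafs, rrs) {
    s4 <- weight(rrs)
    c(e3 = unname(pafs[["e2/e3"]] + pafs[["e3/e3"]] +
                    (1 - s4) * pafs[["e3/e4"]]),
      e4 = unname(pafs[["e2/e4"]] + pafs[["e4/e4"]] + s4 * pafs[["e3/e4"]]),
      share_e4 = s4)
  }
  pt <- split_once(paf_of("paf"), rr_of("estimate"))
  lo <- split_once(paf_of("paf_lower"), rr_of("lower"))
  hi <- split_once(paf_of("paf_upper"), rr_of("upper"))
  out <- tibble::tibble(
    allele = c("e3", "e4"),
    paf = c(pt[["e3"]], pt[["e4"]]),
    paf_lower = c(lo[["e3"]], lo[["e4"]]),
    paf_upper = c(hi[["e3"]], hi[["e4"]])
  )
  structure(out, rule = rule, share_e4 = pt[["share_e4"]],
            class = c("allele_partition", class(out)))
}

#' Baseline-risk sensitivity analysis for OR-derived attributable fractions
#'
#' When risk ratios are obtained from case-control odds ratios, the assumed
#' baseline outcome probability \eqn{p_0} in the reference genotype enters
#' through the OR-to-RR conversion. This runs the full crude-OR → RR(p0) →
#' PAF pipeline at each value of a p0 grid, to show how strongly the total
#' attributable fraction depends on the assumption. For ORs above one the
#' total is monotone decreasing in p0.
#'
#' @param counts A case-control [genotype_counts()] table.
#' @param grid Numeric vector of baseline probabilities in (0, 1).
#' @param reference Reference level.
#' @return Tibble with columns `p0`, `total`, `lower`, `upper` (proportions)
#'   and a list-column `paf_table` holding the full per-genotype table at
#'   each grid point.
#' @export
sensitivity_p0 <- function(counts, grid = seq(0.01, 0.05, by = 0.01),
                           reference = "e2/e2") {
  if (any(grid <= 0 | grid >= 1)) {
    stop("every p0 in the grid must lie in (0, 1)", call. = FALSE)
  }
  ors <- crude_or(counts, reference = reference)
  rows <- lapply(grid, function(p0) {
    pt <- total_paf(counts, convert_or_set(ors, p0))
    tot <- paf_total(pt)
    tibble::tibble(p0 = p0, total = tot[["total"]], lower = tot[["lower"]],
                   upper = tot[["upper"]], paf_table = list(pt))
  })
  do.call(rbind, rows)
}
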