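test_that("crude risk ratio reproduces the two-level carrier estimate from
           the published amyloid-positivity counts", {
  fx <- apoe_fixtures()
  rr <- crude_rr(fx$a4_counts)
  # (1202/4390) / (1/25)
  expect_equal(rr$estimate, 6.8451, tolerance = 1e-4)
  expect_lt(rr$lower, rr$estimate)
  expect_gt(rr$upper, rr$estimate)
})

test_that("crude risk ratio is one for identical risks and invariant to
           doubling all cells, which narrows the interval", {
  t1 <- genotype_counts(c("e2/e2", "e3/e4"), cases = c(10, 20),
                        totals = c(100, 200))
  rr1 <- crude_rr(t1)
  expect_equal(rr1$estimate, 1)
  t2 <- genotype_counts(c("e2/e2", "e3/e4"), cases = c(20, 40),
                        totals = c(200, 400))
  rr2 <- crude_rr(t2)
  expect_equal(rr2$estimate, rr1$estimate)
  expect_lt(rr1$lower, rr2$lower)
  expect_gt(rr1$upper, rr2$upper)
})

test_that("zero case cells error unless the continuity correction is asked
           for", {
  t0 <- genotype_counts(c("e2/e2", "e3/e4"), cases = c(0, 20),
                        totals = c(50, 200))
  expect_error(crude_rr(t0), "zero case count")
  rr <- crude_rr(t0, correction = TRUE)
  expect_true(is.finite(rr$estimate) && rr$estimate > 0)
})

test_that("crude odds ratio matches direct arithmetic on the published
           neuropathology case-control counts", {
  fx <- apoe_fixtures()
  ors <- crude_or(fx$adgc_counts)
  # (623/5) / (10/19)
  expect_equal(ors$estimate[ors$genotype == "e4/e4"], (623 / 5) / (10 / 19),
               tolerance = 1e-12)
  expect_equal(ors$estimate[ors$genotype == "e4/e4"], 236.74,
               tolerance = 1e-4)
})

test_that("odds ratios are one for symmetric tables, multiply across
           reference changes, and error on zero cells by name", {
  sym <- genotype_counts(c("e2/e2", "e3/e3"), cases = c(30, 60),
                         controls = c(10, 20))
  expect_equal(crude_or(sym)$estimate, 1)

  fx <- apoe_fixtures()
  or_ref2 <- crude_or(fx$adgc_counts, reference = "e2/e2")
  or_ref3 <- crude_or(fx$adgc_counts, reference = "e3/e3")
  # OR(a vs c) = OR(a vs b) * OR(b vs c)
  or_44_vs_33 <- or_ref3$estimate[or_ref3$genotype == "e4/e4"]
  or_33_vs_22 <- or_ref2$estimate[or_ref2$genotype == "e3/e3"]
  expect_equal(or_44_vs_33 * or_33_vs_22,
               or_ref2$estimate[or_ref2$genotype == "e4/e4"],
               tolerance = 1e-12)

  z <- genotype_counts(c("e2/e2", "e4/e4"), cases = c(5, 10),
                       controls = c(3, 0))
  expect_error(crude_or(z), "zero cell \\(controls\\)")
  expect_silent(crude_or(z, correction = TRUE))
})

test_that("re-orienting count-backed odds ratios equals recomputing them
           against the new reference, and is an involution", {
  fx <- apoe_fixtures()
  or3 <- crude_or(fx$adgc_counts, reference = "e3/e3")
  re <- reorient_or(or3, "e2/e2")
  direct <- crude_or(fx$adgc_counts, reference = "e2/e2")
  expect_equal(re$estimate[match(direct$genotype, re$genotype)],
               direct$estimate, tolerance = 1e-12)
  expect_equal(re$lower[match(direct$genotype, re$genotype)],
               direct$lower, tolerance = 1e-12)
  # identity when the reference does not change; involution without counts
  expect_identical(reorient_or(or3, "e3/e3"), or3)
  bare <- risk_estimates(c("e3/e3", "e4/e4"), c(2, 8), c(1.5, 5),
                         c(3, 12), measure = "or", reference = "e2/e2")
  back <- reorient_or(reorient_or(bare, "e3/e3"), "e2/e2")
  expect_equal(sort(back$estimate), sort(bare$estimate), tolerance = 1e-12)
})

test_that("odds-to-risk conversion matches a directly constructed two-group
           model and obeys its limits", {
  # reference risk p0 = 0.01; exposed odds = odds0 * OR; compare risk ratio
  p0 <- 0.01
  or <- 236.74
  odds0 <- p0 / (1 - p0)
  exposed_risk <- (odds0 * or) / (1 + odds0 * or)
  expect_equal(or_to_rr(or, p0), exposed_risk / p0, tolerance = 1e-12)
  expect_equal(or_to_rr(or, p0), 70.51, tolerance = 1e-3)

  expect_equal(or_to_rr(1, 0.3), 1)
  # bracketing: RR between 1 and OR for OR > 1, reversed for OR < 1
  for (or in c(0.2, 0.8, 1.5, 12, 300)) {
    for (p0 in c(0.001, 0.05, 0.5)) {
      rr <- or_to_rr(or, p0)
      expect_gte(rr, min(1, or))
      expect_lte(rr, max(1, or))
    }
  }
  # rare-outcome limit and monotone decrease in p0 for OR > 1
  expect_equal(or_to_rr(50, 1e-8), 50, tolerance = 1e-5)
  expect_gt(or_to_rr(50, 0.01), or_to_rr(50, 0.05))
})

test_that("converting a whole OR set preserves interval ordering", {
  fx <- apoe_fixtures()
  rrs <- convert_or_set(crude_or(fx$adgc_counts), 0.01)
  expect_true(all(rrs$lower <= rrs$estimate & rrs$estimate <= rrs$upper))
  expect_match(attr(rrs, "provenance"), "converted-from-or")
})

test_that("genotype-only log-binomial fit equals the crude risk ratios", {
  co <- generate_cohort(cohort_params(n = 60000, baseline_risk = 0.05,
                                      genotype_rr = c(
                                        "e2/e2" = 1, "e2/e3" = 1.5,
                                        "e3/e3" = 2, "e2/e4" = 3,
                                        "e3/e4" = 5, "e4/e4" = 8),
                                      seed = 21L))
  fit <- fit_log_binomial(co)
  crude <- crude_rr(tabulate_genotypes(co))
  expect_equal(unname(fit$estimate[match(crude$genotype, fit$genotype)]),
               crude$estimate, tolerance = 1e-5)
})

test_that("log-binomial parameter recovery on a strong-effect cohort", {
  rr <- c("e2/e2" = 1, "e2/e3" = 1.5, "e3/e3" = 2, "e2/e4" = 4,
          "e3/e4" = 6, "e4/e4" = 10)
  co <- generate_cohort(cohort_params(n = 200000, baseline_risk = 0.02,
                                      genotype_rr = rr, seed = 31L))
  fit <- fit_log_binomial(co)
  i <- match("e4/e4", fit$genotype)
  se_log <- (log(fit$upper[i]) - log(fit$estimate[i])) / qnorm(0.975)
  expect_lt(abs(log(fit$estimate[i]) - log(10)), 3 * se_log)
})

test_that("degenerate outcomes are an explicit convergence failure, not a
           silent estimate", {
  co <- generate_cohort(cohort_params(n = 500, seed = 1L))
  co$outcome <- 0L
  expect_error(fit_log_binomial(co), "degenerate outcome")
  expect_error(fit_logistic(co), "degenerate outcome")
})

test_that("genotype-only logistic fit reproduces the contingency odds
           ratios exactly", {
  fx <- apoe_fixtures()
  cc <- fx$adgc_counts
  co <- tibble::tibble(
    genotype = rep(rep(cc$genotype, 2), c(cc$cases, cc$controls)),
    outcome = rep(rep(c(1L, 0L), each = 6), c(cc$cases, cc$controls))
  )
  fit <- fit_logistic(co)
  ors <- crude_or(cc)
  expect_equal(unname(fit$estimate[match(ors$genotype, fit$genotype)]),
               ors$estimate, tolerance = 1e-6)
})

test_that("shuffled outcomes give near-null odds ratios and rare outcomes
           make converted risk ratios approach the odds ratios", {
  co <- generate_cohort(cohort_params(n = 50000, baseline_risk = 0.05,
                                      genotype_rr = c(
                                        "e2/e2" = 1, "e2/e3" = 1.5,
                                        "e3/e3" = 2, "e2/e4" = 3,
                                        "e3/e4" = 5, "e4/e4" = 8),
                                      seed = 13L))
  set.seed(99)
  co$outcome <- sample(co$outcome)
  fit <- fit_logistic(co)
  expect_true(all(fit$lower < 1 & fit$upper > 1))

  rare <- generate_cohort(cohort_params(n = 500000, baseline_risk = 0.001,
                                        genotype_rr = c(
                                          "e2/e2" = 1, "e2/e3" = 2,
                                          "e3/e3" = 3, "e2/e4" = 5,
                                          "e3/e4" = 8, "e4/e4" = 15),
                                        seed = 17L))
  ors <- fit_logistic(rare)
  rrs <- convert_or_set(ors, 0.001)
  expect_equal(rrs$estimate, ors$estimate, tolerance = 0.02)
})
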