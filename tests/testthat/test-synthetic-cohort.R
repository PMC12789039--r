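test_that("generation is deterministic given params and seed", {
  p <- cohort_params(n = 2000, seed = 42L)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- cohort_params(n = 2000, seed = 43L)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("null risk model yields the baseline outcome rate", {
  rr1 <- setNames(rep(1, 6), apoe_genotypes())
  p <- cohort_params(n = 10000, baseline_risk = 0.02, genotype_rr = rr1,
                     seed = 7L)
  co <- generate_cohort(p)
  # binomial 99% bounds around 0.02 at n = 10,000
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.02) / 10000
  rate <- mean(co$outcome)
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("genotype draws follow the requested frequencies within
           multinomial bounds", {
  # UK-Biobank-like frequencies at the published sample size
  ukb_n <- c("e2/e2" = 1047, "e2/e3" = 21018, "e3/e3" = 100826,
             "e2/e4" = 4208, "e3/e4" = 39974, "e4/e4" = 4032)
  q <- ukb_n / sum(ukb_n)
  p <- cohort_params(n = 171105, genotype_freqs = q, seed = 11L)
  co <- generate_cohort(p)
  obs <- table(co$genotype)
  for (g in apoe_genotypes()) {
    b <- qbinom(c(0.005, 0.995), 171105, q[[g]])
    expect_gte(obs[[g]], b[1])
    expect_lte(obs[[g]], b[2])
  }
})

test_that("generated diplotypes recode to the generated genotype", {
  p <- cohort_params(n = 5000, seed = 3L)
  co <- generate_cohort(p)
  recoded <- code_apoe(co$rs429358, co$rs7412)
  expect_equal(as.character(recoded), as.character(co$genotype))
})

test_that("case-control sampling concentrates case genotypes on the exact
           conditional distribution q*RR / sum(q*RR)", {
  # ADGC-like generative parameters: control-derived frequencies, strong RRs
  q <- c("e2/e2" = 0.019, "e2/e3" = 0.149, "e3/e3" = 0.645,
         "e2/e4" = 0.020, "e3/e4" = 0.157, "e4/e4" = 0.010)
  q <- q / sum(q)
  rr <- c("e2/e2" = 1, "e2/e3" = 2.94, "e3/e3" = 7.21, "e2/e4" = 17.23,
          "e3/e4" = 32.26, "e4/e4" = 70.81)
  p <- cohort_params(genotype_freqs = q, genotype_rr = rr,
                     baseline_risk = 0.01, sampling = "case-control",
                     n_cases = 4018, n_controls = 989, seed = 5L)
  co <- generate_cohort(p)
  expect_equal(sum(co$outcome), 4018)
  case_gt <- table(co$genotype[co$outcome == 1]) / 4018
  expected <- q * rr / sum(q * rr)
  # the modal case genotype is e3/e4, as in the generative truth
  expect_equal(names(which.max(case_gt)), "e3/e4")
  for (g in apoe_genotypes()) {
    b <- qbinom(c(0.005, 0.995), 4018, expected[[g]]) / 4018
    expect_gte(case_gt[[g]], b[1])
    expect_lte(case_gt[[g]], b[2])
  }
})

test_that("closed-form true PAF is zero under the null and reduces to
           Levin's formula for a single exposed level", {
  rr1 <- setNames(rep(1, 6), apoe_genotypes())
  p <- cohort_params(genotype_rr = rr1)
  expect_equal(unname(paf_total(true_paf(p))[["total"]]), 0)

  # two-level populations across a parameter grid
  for (q_e in c(0.05, 0.3, 0.7)) {
    for (rr_e in c(1.5, 4, 25)) {
      q <- setNames(c(1 - q_e, 0, 0, 0, 0, q_e), apoe_genotypes())
      rr <- setNames(c(1, 1, 1, 1, 1, rr_e), apoe_genotypes())
      p <- cohort_params(genotype_freqs = q, genotype_rr = rr,
                         baseline_risk = 0.01)
      expect_equal(unname(paf_total(true_paf(p))[["total"]]),
                   oracle_levin(q_e, rr_e), tolerance = 1e-12)
    }
  }
})

test_that("parameter sets implying individual risks above one are rejected", {
  rr <- setNames(c(1, 1, 1, 1, 1, 30), apoe_genotypes())
  expect_error(cohort_params(baseline_risk = 0.05, genotype_rr = rr),
               "risks above 1")
  expect_error(cohort_params(baseline_risk = 0.01, genotype_rr = rr,
                             beta_age = 2), "risks above 1")
})

test_that("estimation on a large generated cohort recovers the generative
           total PAF within Monte-Carlo error", {
  # the estimate distribution is heavy-tailed (few reference-genotype
  # cases per cohort), so enough replicates are needed for a stable
  # Monte-Carlo standard error
  p_true <- unname(paf_total(true_paf(cohort_params()))[["total"]])
  est <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(n = 100000, seed = s))
    pt <- total_paf(tabulate_genotypes(co),
                    crude_rr(tabulate_genotypes(co)))
    unname(paf_total(pt)[["total"]])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - p_true), 3 * mc_se)
})

test_that("screening that deters affected high-risk carriers biases the
           e4/e4 risk ratio downward", {
  incl <- c("e2/e2" = 1, "e2/e3" = 1, "e3/e3" = 0.9, "e2/e4" = 0.8,
            "e3/e4" = 0.5, "e4/e4" = 0.2)
  q <- hwe_expand(c(e2 = 0.08, e3 = 0.77, e4 = 0.15))
  rr <- c("e2/e2" = 1, "e2/e3" = 1.5, "e3/e3" = 2, "e2/e4" = 4,
          "e3/e4" = 8, "e4/e4" = 20)
  base <- cohort_params(n = 400000, genotype_freqs = q, genotype_rr = rr,
                        baseline_risk = 0.03, seed = 9L)
  scr <- cohort_params(n = 400000, genotype_freqs = q, genotype_rr = rr,
                       baseline_risk = 0.03, sampling = "screened",
                       inclusion_prob = incl, seed = 9L)
  rr_scr <- crude_rr(tabulate_genotypes(generate_cohort(scr)))
  est_44 <- rr_scr$estimate[rr_scr$genotype == "e4/e4"]
  expect_lt(est_44, 20)
})

test_that("cohort tables survive a TSV round trip, recoding genotype from
           the diplotypes", {
  co <- generate_cohort(cohort_params(n = 500, seed = 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.character(back$genotype), as.character(co$genotype))
  expect_equal(back$outcome, co$outcome)
  back2 <- read_cohort(path)
  back2$genotype <- NULL
  # genotype column is re-derived when absent
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co[, setdiff(names(co), "genotype")], tmp)
  rederived <- read_cohort(tmp)
  expect_equal(as.character(rederived$genotype), as.character(co$genotype))
})
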