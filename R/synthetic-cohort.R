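#' Parameters for a synthetic APOE cohort
#'
#' Defines a generative model for individual-level data with known truth,
#' so that every estimation stage can be validated: genotypes are drawn from
#' fixed frequencies, and each subject's outcome is Bernoulli with risk
#' \deqn{p_0 \cdot RR_{g} \cdot \exp(\beta_{age}(age - \bar{age}) +
#' \beta_{sex} \cdot sex),}
#' i.e. multiplicative on the risk scale, matching log-link risk models and
#' keeping the implied attributable fraction closed-form (see [true_paf()]).
#'
#' Defaults emulate a UK-Biobank-like population aged 60+: the published
#' genotype frequencies of that sample, its published per-genotype
#' Alzheimer's-disease risk ratios against e2/e2, a 1% baseline risk in
#' e2/e2, age ~ Normal(64.1, 2.8) years and sex ~ Bernoulli(0.5). Covariate
#' effects default to zero so crude and adjusted estimands coincide.
#'
#' @param n Number of subjects (for `sampling = "case-control"`, ignored in
#'   favour of `n_cases` + `n_controls`).
#' @param genotype_freqs Named probabilities over the six genotypes, summing
#'   to 1. Overrides `allele_freqs`.
#' @param allele_freqs Alternatively, named probabilities of the e2/e3/e4
#'   alleles, expanded to genotype frequencies under Hardy-Weinberg
#'   proportions.
#' @param baseline_risk Outcome probability in e2/e2 (p0), in (0, 1).
#' @param genotype_rr Named positive risk ratios per genotype; the e2/e2
#'   entry must be 1.
#' @param beta_age,beta_sex Log-scale covariate effects (per year centred at
#'   `age_mean`, and for sex = 1).
#' @param age_mean,age_sd Age distribution parameters (years).
#' @param sampling `"cohort"` (simple random sample), `"case-control"`
#'   (fixed numbers of cases and controls drawn from the genotype
#'   distributions the model implies among cases and non-cases), or
#'   `"screened"` (affected subjects enrol with per-genotype inclusion
#'   probabilities while unaffected subjects always enrol, emulating
#'   selective volunteering of cognitively intact participants; inclusion
#'   probabilities decreasing in genotype risk bias the high-risk RRs
#'   downward, a qualitative device only).
#' @param n_cases,n_controls Sample sizes for case-control sampling.
#' @param inclusion_prob Named per-genotype inclusion probabilities for
#'   screened sampling.
#' @param seed Integer RNG seed; generation is reproducible given the seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n = 10000,
                          genotype_freqs = NULL,
                          allele_freqs = NULL,
                          baseline_risk = 0.01,
                          genotype_rr = NULL,
                          beta_age = 0, beta_sex = 0,
                          age_mean = 64.1, age_sd = 2.8,
                          sampling = c("cohort", "case-control", "screened"),
                          n_cases = NULL, n_controls = NULL,
                          inclusion_prob = NULL,
                          seed = 1L) {
  sampling <- match.arg(sampling)
  gt <- apoe_genotypes()

  # config files hand these over as lists
  if (is.list(genotype_freqs)) genotype_freqs <- unlist(genotype_freqs)
  if (is.list(allele_freqs)) allele_freqs <- unlist(allele_freqs)
  if (is.list(genotype_rr)) genotype_rr <- unlist(genotype_rr)

  if (is.null(genotype_freqs)) {
    if (!is.null(allele_freqs)) {
      genotype_freqs <- hwe_expand(allele_freqs)
    } else {
      # UK-Biobank-like genotype distribution (sample aged >= 60)
      genotype_freqs <- c("e2/e2" = 1047, "e2/e3" = 21018,
                          "e3/e3" = 100826, "e2/e4" = 4208,
                          "e3/e4" = 39974, "e4/e4" = 4032) / 171105
    }
  }
  if (!all(gt %in% names(genotype_freqs))) {
    stop("genotype_freqs must name all six genotypes", call. = FALSE)
  }
  genotype_freqs <- genotype_freqs[gt]
  if (any(genotype_freqs < 0) || abs(sum(genotype_freqs) - 1) > 1e-8) {
    stop("genotype frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }

  if (is.null(genotype_rr)) {
    # UK-Biobank-like AD risk ratios vs e2/e2
    genotype_rr <- c("e2/e2" = 1, "e2/e3" = 1.68, "e3/e3" = 2.19,
                     "e2/e4" = 4.03, "e3/e4" = 8.39, "e4/e4" = 23.36)
  }
  if (!all(gt %in% names(genotype_rr))) {
    stop("genotype_rr must name all six genotypes", call. = FALSE)
  }
  genotype_rr <- genotype_rr[gt]
  if (any(genotype_rr <= 0)) stop("risk ratios must be positive",
                                  call. = FALSE)
  if (abs(genotype_rr[["e2/e2"]] - 1) > 1e-12) {
    stop("the e2/e2 reference must have RR = 1", call. = FALSE)
  }
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    stop("baseline_risk must lie in (0, 1)", call. = FALSE)
  }

  # reject parameter sets whose maximum achievable individual risk exceeds 1;
  # the covariate multiplier is bounded at 4 SD of age plus the sex effect
  max_cov <- exp(abs(beta_age) * 4 * age_sd + max(0, beta_sex))
  if (baseline_risk * max(genotype_rr) * max_cov > 1) {
    stop("parameter set implies individual risks above 1 ",
         "(baseline_risk * max RR * max covariate multiplier > 1)",
         call. = FALSE)
  }

  if (sampling == "case-control") {
    if (is.null(n_cases) || is.null(n_controls)) {
      stop("case-control sampling needs n_cases and n_controls",
           call. = FALSE)
    }
  }
  if (sampling == "screened") {
    if (is.null(inclusion_prob) || !all(gt %in% names(inclusion_prob))) {
      stop("screened sampling needs per-genotype inclusion_prob",
           call. = FALSE)
    }
    inclusion_prob <- inclusion_prob[gt]
    if (any(inclusion_prob < 0 | inclusion_prob > 1)) {
      stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
    }
  }

  structure(list(n = n, genotype_freqs = genotype_freqs,
                 baseline_risk = baseline_risk, genotype_rr = genotype_rr,
                 beta_age = beta_age, beta_sex = beta_sex,
                 age_mean = age_mean, age_sd = age_sd,
                 sampling = sampling, n_cases = n_cases,
                 n_controls = n_controls, inclusion_prob = inclusion_prob,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Expand allele frequencies to Hardy-Weinberg genotype frequencies
#'
#' @param allele_freqs Named probabilities for e2, e3 and e4, summing to 1.
#' @return Named six-genotype frequency vector.
#' @export
hwe_expand <- function(allele_freqs) {
  if (!all(c("e2", "e3", "e4") %in% names(allele_freqs))) {
    stop("allele_freqs must name e2, e3 and e4", call. = FALSE)
  }
  f <- allele_freqs[c("e2", "e3", "e4")]
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop("allele frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  c("e2/e2" = f[["e2"]]^2,
    "e2/e3" = 2 * f[["e2"]] * f[["e3"]],
    "e3/e3" = f[["e3"]]^2,
    "e2/e4" = 2 * f[["e2"]] * f[["e4"]],
    "e3/e4" = 2 * f[["e3"]] * f[["e4"]],
    "e4/e4" = f[["e4"]]^2)
}

subject_risk <- function(p, genotype, age, sex) {
  risk <- p$baseline_risk * p$genotype_rr[genotype] *
    exp(p$beta_age * (age - p$age_mean) + p$beta_sex * sex)
  pmin(risk, 1)  # clip: the 4-SD rejection bound can be exceeded in a tail
}

#' Generate a synthetic individual-level APOE cohort
#'
#' Draws subjects under the generative model of [cohort_params()] and
#' returns an individual-level table including the rs429358/rs7412
#' diplotypes implied by each genotype (for e2/e4 subjects this is the
#' ambiguous double heterozygote, so re-coding the table exercises the
#' ambiguity policy of [code_apoe()]).
#'
#' Case-control sampling draws case genotypes from the exact conditional
#' distribution \eqn{q_i RR_i / \sum_j q_j RR_j} and control genotypes from
#' \eqn{q_i (1 - p_0 RR_i) / \sum_j q_j (1 - p_0 RR_j)} (valid because
#' covariate effects are generated independently of genotype); screened
#' sampling generates a cohort of size `n` and keeps each subject with the
#' genotype's inclusion probability.
#'
#' @param params A `cohort_params` object.
#' @return Tibble with columns `sample_id`, `rs429358`, `rs7412`,
#'   `genotype`, `age`, `sex`, `outcome`; the parameters are attached as
#'   attribute `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  gt <- apoe_genotypes()
  set.seed(p$seed)

  if (p$sampling == "case-control") {
    q <- p$genotype_freqs
    rr <- p$genotype_rr
    w_case <- q * rr / sum(q * rr)
    w_ctrl <- q * (1 - p$baseline_risk * rr)
    w_ctrl <- w_ctrl / sum(w_ctrl)
    genotype <- c(sample(gt, p$n_cases, replace = TRUE, prob = w_case),
                  sample(gt, p$n_controls, replace = TRUE, prob = w_ctrl))
    outcome <- rep(c(1L, 0L), c(p$n_cases, p$n_controls))
    n <- p$n_cases + p$n_controls
    age <- stats::rnorm(n, p$age_mean, p$age_sd)
    sex <- stats::rbinom(n, 1, 0.5)
  } else {
    n <- p$n
    genotype <- sample(gt, n, replace = TRUE, prob = p$genotype_freqs)
    age <- stats::rnorm(n, p$age_mean, p$age_sd)
    sex <- stats::rbinom(n, 1, 0.5)
    risk <- subject_risk(p, genotype, age, sex)
    outcome <- stats::rbinom(n, 1, risk)
    if (p$sampling == "screened") {
      # selective volunteering acts on affected subjects: individuals with
      # the outcome enrol with the genotype's inclusion probability,
      # unaffected individuals always enrol. Purely genotype-based thinning
      # would leave within-genotype risks (hence RRs) unbiased.
      keep <- outcome == 0L | stats::runif(n) < p$inclusion_prob[genotype]
      genotype <- genotype[keep]
      age <- age[keep]
      sex <- sex[keep]
      outcome <- outcome[keep]
      n <- sum(keep)
    }
  }

  dip <- apoe_diplotype(genotype)
  out <- tibble::tibble(
    sample_id = sprintf("S%06d", seq_len(n)),
    rs429358 = dip$rs429358,
    rs7412 = dip$rs7412,
    genotype = factor(genotype, levels = gt),
    age = age,
    sex = sex,
    outcome = outcome
  )
  attr(out, "params") <- p
  out
}

#' Closed-form attributable fraction implied by generative parameters
#'
#' Under the multiplicative generative model the fraction of cases arising
#' in genotype i is \eqn{p_{ci} = q_i RR_i / \sum_j q_j RR_j} (covariate
#' effects cancel when independent of genotype), so the implied per-genotype
#' and total attributable fractions follow in closed form from the
#' multi-level formula. This is the ground truth that estimates from
#' generated cohorts should recover.
#'
#' @param params A `cohort_params` object.
#' @return A `paf_table` over the five risk genotypes (no confidence
#'   interval: the truth is a point).
#' @export
true_paf <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  q <- params$genotype_freqs
  rr <- params$genotype_rr
  p_ci <- q * rr / sum(q * rr)
  est <- risk_estimates(apoe_risk_genotypes(),
                        estimate = unname(rr[apoe_risk_genotypes()]),
                        lower = unname(rr[apoe_risk_genotypes()]),
                        upper = unname(rr[apoe_risk_genotypes()]),
                        measure = "rr", reference = "e2/e2",
                        provenance = "generative-truth")
  total_paf(p_ci, est)
}

#' Read / write individual-level cohort tables as TSV
#'
#' Columns: `sample_id`, `rs429358`, `rs7412`, `genotype` (optional on
#' read; re-derived with [code_apoe()] when absent), `age`, `sex`,
#' `outcome`.
#'
#' @param cohort Cohort tibble (e.g. from [generate_cohort()]).
#' @param path File path.
#' @param ambiguity_policy Passed to [code_apoe()] when re-deriving
#'   genotypes on read.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, ambiguity_policy = "e2/e4") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("sample_id", "rs429358", "rs7412", "outcome")
  if (!all(needed %in% names(df))) {
    stop("cohort TSV must contain columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!"genotype" %in% names(df)) {
    df$genotype <- code_apoe(df$rs429358, df$rs7412,
                             ambiguity_policy = ambiguity_policy)
  } else {
    df$genotype <- factor(df$genotype, levels = apoe_genotypes())
  }
  df
}
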