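---
title: "Attributable fractions for APOE genotypes: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions for APOE genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoepaf)
```

## The estimand

A population attributable fraction (PAF) is the proportion of cases that
would not occur if an exposure's excess risk were removed. For a
multi-level categorical exposure — here the six *APOE* ε-genotypes — the
appropriate form sums per-level contributions,

$$\mathrm{PAF} = \sum_{i} p_{ci}\,\frac{RR_i - 1}{RR_i},$$

where $p_{ci}$ is the fraction of all cases in exposure level $i$ and
$RR_i$ the risk ratio of level $i$ against the reference. Two modelling
choices matter and are fixed throughout the package:

* **The reference is ε2/ε2**, the lowest-risk genotype, not the common
  ε3/ε3. Attributable fractions answer "what if everyone had the lowest
  risk?", so referencing on anything else understates the burden — in
  particular it hides the sizeable contribution of ε3, which is
  risk-increasing relative to ε2 despite being the majority allele.
* **Per-level case fractions, not prevalences**, enter the formula. A
  recurring error in this literature is plugging exposure prevalence (or
  allele frequency) into Levin's two-level formula
  $q_e(RR-1)/(1+q_e(RR-1))$; the case-fraction form is algebraically
  equivalent only when case fractions and prevalence are mutually
  consistent, and generalises correctly to multiple levels. The
  equivalence on two levels, and the exact identity between the formula
  and brute-force excess-case counting
  $(\text{observed} - \sum_i a_i/RR_i)/\text{observed}$, are both
  enforced in the test suite.

## Genotype coding

ε-genotypes are coded from unphased diplotypes at rs429358 and rs7412 with
haplotype definitions ε2 = (T,T), ε3 = (T,C), ε4 = (C,C). Of the nine
diplotype combinations, six map uniquely; three can only be explained by
the vanishingly rare fourth haplotype (C,T) ("ε1") and return missing
rather than erroring, since anomalous-allele samples are excluded, not
rejected, in practice. The double heterozygote (C/T at both SNPs) is
consistent with both ε2/ε4 and ε1/ε3; the default policy assigns ε2/ε4
because ε1 is negligible, and the policy is an explicit argument of
`code_apoe()` so the choice is always visible. `hwe_test()` provides the
standard genotyping-quality check: a triallelic Hardy–Weinberg chi-square
on 3 degrees of freedom (6 classes − 1 − 2 free allele frequencies),
asymptotic by design — an exact test adds little at biobank scale.

## Risk estimation

`crude_rr()` and `crude_or()` implement contingency-table estimates with
Wald intervals on the log scale. Wald intervals are used throughout for
consistency; a Haldane–Anscombe 0.5 continuity correction is available but
**off by default** — zero cells stop with the offending cell named,
because silently shifted estimates are worse than an error.

Model-based estimation goes through `stats::glm`: `fit_log_binomial()`
(binomial family, log link — coefficients are log-RRs) and
`fit_logistic()`. Log-binomial models are the natural choice since RRs
feed the PAF formula directly, but their IRLS fitting fails when fitted
probabilities approach one (high-risk ε4/ε4 strata). On non-convergence
the function *stops with a diagnostic* recommending the logistic +
conversion path rather than switching automatically: which effect measure
to model is an analyst decision per dataset, and a silent fallback would
change the estimand. Degenerate outcomes (all 0 or all 1) are rejected up
front.

When only odds ratios are available they are converted with
$RR = OR/(1 - p_0 + p_0\,OR)$, where $p_0$ is the assumed outcome
probability in the reference genotype. The conversion is applied
*identically to the point estimate and both confidence limits*
(`convert_or_set()`), matching the plug-in treatment of intervals
downstream. For $OR > 1$ the result is bracketed between 1 and the OR and
decreases in $p_0$; `sensitivity_p0()` exposes the dependence by running
the whole crude-OR → RR($p_0$) → PAF pipeline over a $p_0$ grid (default
1–5%, where totals move by only a few percentage points).
`reorient_or()` re-references a published OR set onto ε2/ε2; when the
underlying counts are attached the re-oriented set is recomputed exactly,
otherwise bounds are divided by bounds — an approximation that ignores the
covariance between the two log-ORs, and is labelled as such in the
provenance string.

## Confidence intervals and the allele partition

PAF intervals are plug-in: the per-level formula re-evaluated at the lower
and upper RR limits and summed. This propagates only RR uncertainty —
sampling error in the case fractions is ignored — so the intervals are
anti-conservative; they are used because they are the convention for this
estimator, and the limitation is stated rather than patched.

`partition_alleles()` splits the five-genotype total between ε3 and ε4.
The ε2/ε3 and ε3/ε3 contributions belong to ε3, ε2/ε4 and ε4/ε4 to ε4;
the mixed ε3/ε4 genotype is divided by a rule. The default
`"rr-proportional"` rule gives ε4 the share
$RR(\varepsilon2/\varepsilon4) / (RR(\varepsilon2/\varepsilon3) +
RR(\varepsilon2/\varepsilon4))$ — each allele's single-copy risk on an ε2
background — which reproduces the published 56.9%/35.8% split on the ADGC
inputs to printed rounding; an `"excess-rr-proportional"` ($RR-1$ weights)
alternative is provided because the split rule is genuinely a modelling
choice, and the rule used is recorded in the output. Under either rule the
two shares close exactly on the five-genotype total. The published
partition *intervals* are not reproduced by plug-in evaluation at the RR
bounds under either rule, so the partition CIs here are documented as
plug-in approximations and only the point estimates are treated as
reference values.

## GWAS-locus PAFs

`locus_paf()` extends the machinery to any biallelic locus summarised by a
risk-allele frequency and per-allele OR: genotype frequencies by
Hardy–Weinberg proportions, genotype ORs $(1, OR, OR^2)$ under the default
multiplicative model (the standard GWAS summary-statistic assumption) or
$(1, OR, OR)$ under a dominant/carrier model, conversion to RRs at an
assumed $p_0$, and *implied* case fractions $q_i RR_i / \sum_j q_j RR_j$.
Because no individual-level case data enter, the output records
`case_fraction_source = "hwe-implied"` and the $p_0$ used. `rank_loci()`
orders loci by PAF with a stable locus-id tie-break. PAFs of distinct loci
can overlap and may sum above 100%; no overlap decomposition is attempted.

## The synthetic-cohort generator

`generate_cohort()` exists so the whole pipeline is testable without
individual-level biobank data. The generative model is deliberately the
model the estimators assume: genotypes from fixed frequencies; outcome
Bernoulli with risk $p_0 \cdot RR_g \cdot \exp(\beta_{age}(age -
\bar{age}) + \beta_{sex}\,sex)$, multiplicative on the risk scale so the
implied PAF is closed-form (`true_paf()`: case fractions
$q_i RR_i/\sum q_j RR_j$). Defaults describe a UK-Biobank-like population
aged 60+: its published genotype frequencies and per-genotype AD risk
ratios, $p_0 = 1\%$, age $\sim N(64.1, 2.8^2)$ years, sex
Bernoulli(0.5), covariate effects zero so crude and adjusted estimands
coincide. Parameter sets whose maximum achievable risk exceeds one are
rejected at construction (the covariate multiplier is bounded at 4 SD of
age); residual tail risks are clipped at one. Each subject also carries
the diplotype its genotype implies — ε2/ε4 subjects deliberately emit the
ambiguous double heterozygote, so round-trip tests exercise the coding
policy.

Three sampling designs:

* **cohort** — a simple random sample;
* **case-control** — case genotypes drawn from the exact conditional
  distribution $q_i RR_i/\sum q_j RR_j$ and controls from
  $q_i(1 - p_0 RR_i)/\sum q_j (1 - p_0 RR_j)$, valid because covariates
  are generated independently of genotype;
* **screened** — a qualitative device for volunteer/screening selection:
  *affected* subjects enrol with a per-genotype inclusion probability
  while unaffected subjects always enrol. Thinning by genotype alone
  would be independent of outcome given genotype and could not bias
  within-genotype risks; making inclusion act on affected individuals
  reproduces the mechanism suspected in amyloid-screening trials, where
  high-risk carriers with established impairment are less likely to
  volunteer and pass cognitive screening, biasing their estimated RRs
  downward.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: follow-up time and competing mortality,
relatedness and population structure, covariate–genotype dependence,
outcome misclassification, and the EHR ascertainment process. It validates
the estimators under their own assumptions, nothing more.

## Validation scale and numerical choices

Parameter recovery is checked on cohorts of n = 100,000 (about the scale
at which an ε2/ε2 reference group becomes usable: ~600 subjects, ~6
expected reference cases at the default 1% baseline) over 20 Monte-Carlo
replicates; the per-seed estimate distribution is heavy-tailed at this
reference-group size, so the replicate count is chosen to stabilise the
Monte-Carlo standard error, and the seed-averaged estimate is required to
fall within 3 such SEs of the closed-form truth. Published-value
reproductions (ADGC, A4, FinnGen fixtures) are exact arithmetic and run in
well under a second. Fixture count tables are integrity-checked against
their published sample totals (4018/989 ADGC cases/controls, 4415 A4
subjects, 1203 amyloid-positive) at every load. All internal arithmetic is
full precision; percentages are rounded to one decimal and RRs to two only
in the report layer, mirroring the conventional table layout. The pipeline
runner logs every numeric default in force — baseline probability, SUVr
positivity threshold (1.15), partition rule, ambiguity policy, seed — and
MD5 digests of all file inputs, so no constant is silent.

## Known limitations

* PAF intervals (and the allele-partition intervals especially) are
  plug-in and anti-conservative.
* The counts-path reproduction of OR-derived RRs differs from published
  values by up to ~3% for sparse genotype rows, because published
  analyses used covariate-adjusted source ORs; both paths are reported
  side by side rather than reconciled.
* The screened sampling mode is directional and qualitative; no attempt
  is made to calibrate it to a real screening process.
* Attributable fractions assume the exposure is causal and the RRs
  unbiased; nothing in the package can verify that from summary inputs.
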