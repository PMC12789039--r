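# apoepaf

Estimating the proportion of Alzheimer's disease (AD), all-cause dementia
and cerebral amyloidosis attributable to the common *APOE* risk alleles —
and, more generally, multi-level population attributable fractions (PAFs)
for genotype exposures.

## The problem

The three common *APOE* alleles (ε2, ε3, ε4) are defined by haplotypes of
two SNPs, rs429358 and rs7412. Relative to the lowest-risk ε2/ε2 genotype,
every other genotype raises AD risk — not only ε4 carriage but ε3 as well,
which is commonly mistaken for neutral. Quantifying the disease burden
attributable to the five risk-increasing genotypes therefore requires
modelling risk against an ε2/ε2 reference (rare, so large samples are
needed), and a PAF formula that handles a multi-level exposure:

    PAF = Σᵢ p_ci · (RRᵢ − 1) / RRᵢ

where `p_ci` is the fraction of cases with genotype *i* and `RRᵢ` its risk
ratio against ε2/ε2. When only odds ratios are estimable (case-control
designs, logistic models), they are first converted with

    RR = OR / (1 − p₀ + p₀·OR)

for an assumed baseline outcome probability `p₀` in ε2/ε2 individuals.
Confidence intervals for PAFs are plug-in: the formula is re-evaluated at
the lower and upper RR confidence limits.

The package implements this pipeline end to end for whoever needs
attributable fractions for categorical genetic exposures: genotype coding
from diplotypes (with an explicit policy for the ambiguous double
heterozygote), Hardy–Weinberg checks, crude and model-based (log-binomial /
logistic) risk estimation, OR re-orientation to a new reference, OR→RR
conversion, multi-level PAFs with allele-wise partitioning of the ε3/ε4
genotype's contribution, PAFs for arbitrary biallelic GWAS loci, and a
synthetic-cohort generator with closed-form true PAFs so every stage can be
validated without access to individual-level biobank data. Published count
tables and risk estimates from four samples (ADGC, UK Biobank, FinnGen, A4)
are bundled as fixtures with reproduction recipes.

## Worked example

```r
library(apoepaf)
print(reproduce_adgc())
```

```
== ADGC reproduction (p0 = 0.01 ) ==
-- published-RR path --
Population attributable fractions vs e2/e2 [published (converted from ORs, p0 = 0.01)]
 genotype    RR   PAF (95% CI), %
    e2/e3  2.94    1.9 (0.8, 2.3)
    e3/e3  7.21 27.3 (20.1, 29.8)
    e2/e4 17.23    2.5 (2.1, 2.6)
    e3/e4 32.26 45.7 (43.4, 46.4)
    e4/e4 70.81 15.3 (15.0, 15.3)
Total: 92.7 (81.4, 96.5)
Allele partition (rr-proportional): e3 35.8%, e4 56.9%
-- counts path --
Population attributable fractions vs e2/e2 [converted-from-or(p0=0.01)]
 genotype    RR   PAF (95% CI), %
    e2/e3  2.87    1.8 (0.2, 2.4)
    e3/e3  7.11 27.2 (20.2, 29.8)
    e2/e4 17.04    2.5 (2.2, 2.6)
    e3/e4 31.96 45.7 (44.0, 46.4)
    e4/e4 70.51 15.3 (15.1, 15.3)
Total: 92.6 (81.8, 96.6)
-- sensitivity to p0 --
   p0     total     lower     upper
 0.01 0.9258734 0.8179257 0.9656004
 0.02 0.9165212 0.8096639 0.9558469
 0.03 0.9071689 0.8014020 0.9460933
 0.04 0.8978167 0.7931401 0.9363398
 0.05 0.8884644 0.7848782 0.9265863
```

Reading this: in the ADGC neuropathologically confirmed case-control
sample, 92.7% of AD cases are attributable to carrying ε3 or ε4 rather than
ε2/ε2 — 56.9% to the ε4 allele and 35.8% to ε3. The "published-RR path"
injects the published per-genotype risk ratios; the "counts path" rebuilds
them from the raw genotype counts (crude ORs → ε2/ε2 reference → RRs at a
1% baseline risk) and lands within 0.1 percentage points, the residual
reflecting the source study's covariate adjustment. The sensitivity block
shows the total moving by under 4 percentage points as the assumed baseline
risk varies from 1% to 5%.

Simulation-backed validation works the same way:

```r
params <- cohort_params(n = 100000, seed = 1)      # UK-Biobank-like defaults
cohort <- generate_cohort(params)
tab    <- tabulate_genotypes(cohort)
paf_total(total_paf(tab, crude_rr(tab)))           # estimate ...
paf_total(true_paf(params))                        # ... vs closed-form truth
```

A thin command-line wrapper (`inst/scripts/apoepaf.R`) exposes the same
operations as subcommands (`run`, `simulate`, `reproduce-adgc`,
`reproduce-a4`, `locus-paf`) over YAML/JSON configs.

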