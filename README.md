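# prsrisk

Risk stratification of breast cancer by polygenic risk score (PRS) in
population cohorts, from genotype dosages to absolute lifetime risk.

The package is aimed at statistical geneticists and cancer epidemiologists
who have (i) a published PRS weight set, (ii) genotype dosages for a cohort,
(iii) case/control phenotypes with entry and exit ages, and (iv) registry
age-specific incidence and all-cause mortality tables — and who want the
standard stratification read-outs: how well the PRS discriminates cases from
controls, how strongly it shifts the age at onset, and what absolute risk a
woman at a given PRS percentile faces over her lifetime or the next decade.

## The model

**Scoring.** The PRS of sample *j* is the additive dosage sum
PRS*j* = Σ*i* a*ij* β*i*, with a*ij* ∈ {0, 1, 2} the effect-allele dosage and
β*i* the published per-allele log-odds weight; no clumping, pruning or
p-value thresholding. Scores are z-standardized over the whole cohort, so
every downstream effect size is "per 1 SD of PRS". Variant harmonization
matches by rsID, re-orients swapped allele pairs (dosage → 2 − dosage) and
drops strand-ambiguous palindromic (A/T, C/G) variants.

**Discrimination.** ROC AUC as the Mann–Whitney probability
P(z_case > z_control) + ½P(tie), and the odds ratio per SD from
maximum-likelihood logistic regression of status on z.

**Age at onset.** A left-truncated, right-censored Cox model on the age
scale, h(t, x) = λ₀(t)·exp(b·x): the risk set at an event age t contains the
samples with entry_age < t ≤ exit_age. The partial likelihood is maximized
by Newton's method with the Efron tie correction; exp(b) is the hazard ratio
per SD, and Harrell's concordance index is computed over the same
truncation-aware comparable pairs.

**Absolute risk.** An absolute-risk model in the iCare family: the baseline
hazard λ₀(t) is calibrated so that the model, averaged over the
still-disease-free score distribution (susceptible depletion), reproduces
the registry marginal incidence λ_m(t); the τ-year risk of a woman aged *a*
with score z is then

R(a, a+τ) = ∫ₐ^{a+τ} λ₀(t) e^{bz} · exp(−∫ₐᵗ (λ₀(u) e^{bz} + m(u)) du) dt,

with m(t) the all-cause mortality rate as a competing risk, evaluated
grid-exactly on 1-year steps. Percentile curves fix z at standard-normal
quantiles (1st/25th/50th/75th/90th/99th by default).

A synthetic-data module generates every input with known ground truth —
Hardy–Weinberg dosages over a MAF spectrum, Gaussian weight sets,
Nordic-shaped incidence plus Gompertz mortality, and left-truncated
proportional-hazards onset cohorts — so the whole pipeline is testable
without access-restricted cohort data.

## Worked example

A fully simulated run (2,500 subjects, 80 variants, true HR per SD 1.494):

```r
library(prsrisk)
cfg <- list(seed = 1,
            simulate = list(n_samples = 2500, n_variants = 80,
                            true_b = log(1.494)))
rep <- run_full_analysis(cfg)
print(rep)
```

```
PRS risk-stratification run (seed 1)

harmonization: 80 of 80 model variants used ( 0 flipped, 0 dropped )

PRS discrimination (230 cases / 2252 controls)
  AUC       0.6401
  OR per SD 1.686 (SE log 0.072, 95% CI 1.464-1.942)

Left-truncated right-censored Cox fit (efron ties)
  n = 2482, events = 230
  b = 0.5121 (se 0.0673), HR = 1.669 (95% CI 1.463-1.904)
  concordance = 0.6475 (se 0.0189)

cumulative risk (%) by percentile at milestone ages:
      50    60    70    80
p01 0.45  1.00  1.68  2.33
p25 1.05  2.31  3.87  5.33
p50 1.48  3.25  5.43  7.44
p75 2.08  4.56  7.58 10.34
p90 2.83  6.17 10.19 13.82
p99 4.79 10.30 16.74 22.35

observed cases per PRS decile:
 [1] 10 14 17 23 15 14 25 25 38 49
```

Reading the output: the simulated PRS separates cases from controls with
AUC 0.64, shifts onset with a fitted hazard ratio of 1.67 per SD (the true
CI covers the generative 1.494 at this sample size), and the calibrated
absolute-risk model puts a 99th-percentile woman at a 22% cumulative risk
by age 80 versus 7.4% at the median — with the observed decile case counts
rising accordingly. With file inputs, replace the `simulate` block by paths
(`weights:`, `dosages:`, `phenotypes:`, `incidence:`, `mortality:`); the
same run is available from a shell via
`Rscript inst/scripts/bcprs.R --config run.yaml --outdir out/`.

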