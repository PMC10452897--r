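---
title: "Methods: PRS stratification and absolute risk with competing mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS stratification and absolute risk with competing mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsrisk)
```

# The problem

A polygenic risk score (PRS) compresses thousands of small genotype effects
into one number per woman. Used for breast-cancer screening it must answer
three questions: does the score separate women who will develop disease
from those who will not (discrimination), does a higher score mean earlier
onset (hazard), and what probability of disease does a given score imply
over a stated age window, given that death from other causes competes
(absolute risk)? `prsrisk` implements that chain end to end and ships
generators that produce every input with known truth, because the cohorts
such analyses are run on are typically access-restricted.

# Scoring and its conventions

The score is the plain additive sum `sum_i a_ij * beta_i` over the variants
of a published weight set, `a_ij` the effect-allele dosage. Three
conventions matter and are all pinned by tests:

* **Harmonization.** Matching is by rsID, not chromosome:position —
  published breast-cancer weight sets identify variants by rsID, and
  positions move between genome builds. A genotype variant whose declared
  allele pair is the model's pair swapped is re-oriented (`2 - dosage`);
  palindromic A/T and C/G variants are dropped unconditionally, with no
  frequency-based rescue, because strand cannot be resolved from alleles
  alone and a deterministic, conservative rule keeps the loss visible in
  the harmonization report. Dosage files whose headers do not declare
  alleles are handled by policy (`unknown_alleles`), defaulting to drop.
* **Missing dosages** are mean-imputed per variant (the default behaviour
  of mainstream scoring software), which leaves the cohort mean raw score
  identical to the complete-case mean — a property the suite asserts.
* **Standardization** is plain z-scoring over the entire pooled cohort
  (cases and controls), with the population (divide-by-N) SD convention.
  We read "standardized to a Gaussian" as z-scoring, not a rank-based
  inverse-normal transform: the scoring formula is linear and downstream
  effect sizes are defined per SD, which only requires centering and
  scaling. Standardizing over the final analysis cohort (after any sample
  exclusions) is the default; callers who standardize earlier can pass
  scores through unchanged since the operation is idempotent.

# Discrimination

AUC is computed as the Mann–Whitney statistic with half credit for ties
(identical to trapezoidal ROC integration); the tie rule is stated because
integer-valued dosage sums can tie. The odds ratio per SD comes from a
logistic regression of status on the standardized score with no covariates,
fitted by IRLS to `|delta| < 1e-8` (coefficient scale, 100-iteration cap),
with the SE of the log-odds coefficient from the observed information.
The "SE" we report is the SE of the log coefficient, the quantity Wald
intervals need. Complete separation is detected (diverging coefficient or
vanishing weights) and raised as an error rather than reported as a huge
finite OR.

# The age-at-onset model

The Cox model `h(t, x) = lambda0(t) exp(b x)` is fitted on the **age**
time scale: entry age is the age at cohort enrolment, exit age the age at
diagnosis (cases) or last follow-up (controls). Cohorts assembled from
registries are left-truncated — a woman enrolled at 45 could not have been
observed to develop disease at 40 — so the risk set at an event age `t`
contains exactly the samples with `entry_age < t <= exit_age`. The partial
likelihood is maximized by Newton's method with step-halving, declared
converged when the log-likelihood moves by less than 1e-9; the SE is the
inverse observed information. Efron's tie correction is the default
because ages recorded in whole years tie frequently; Breslow is available
behind a flag. The implementation is checked against `survival::coxph` to
1e-6 on truncated and untruncated data, and against a brute-force partial
likelihood (risk sets built by definition, optimized by 1-D grid/golden
search) on small toys.

Harrell's C uses the same truncation-aware comparability rule: `(i, j)`
comparable when `i` has an event at `t_i` and `j` is under observation at
that age. Two events tied in time enter the pair set in both directions
and so contribute exactly 1/2 — a marginal difference from the textbook
convention of excluding them, invisible on continuous ages. The SE is a
per-event cluster (Noether-type U-statistic) estimator.

Controls diagnosed with other cancers should be excluded upstream, not
censored here; the model takes the cohort as given.

# Absolute risk with competing mortality

The τ-year absolute risk of a woman aged `a` with score `z` is

$$R(a, a+\tau) = \int_a^{a+\tau} \lambda_0(t)\, e^{bz}
  \exp\!\Big(-\int_a^t \big(\lambda_0(u) e^{bz} + m(u)\big)\,du\Big)\,dt,$$

with `m(t)` the all-cause mortality hazard. Registry rates are published as
step functions (per 100,000 person-years in integer-year bins, converted
exactly ×1e−5 on read), so instead of generic quadrature the integral is
evaluated with exact piecewise-exponential algebra on a 1-year grid: within
a year with disease hazard `lam` and mortality `m`, the onset probability
is `S * lam/(lam+m) * (1 - exp(-(lam+m)))` and the carried survival factor
multiplies by `exp(-(lam+m))`. This makes the window-additivity identity
`R(a, t1+t2) = R(a, t1) + S(a, t1) R(a+t1, t2)` hold to 1e-12, which the
suite asserts, and removes grid-refinement questions entirely. Other
absolute-risk engines integrate on internal grids of their own choosing, so
third decimals may differ.

## Baseline-hazard calibration

The registry publishes the *marginal* incidence `lambda_m(t)`, not the
baseline `lambda_0(t)` of the proportional-hazards model. Setting
`lambda_0 = lambda_m / E[e^{bZ}]` ignores that high-score women are
depleted from the disease-free population as age advances, which biases
late-age risks. The default calibration therefore tracks susceptible
depletion: the standard-normal referent is represented by `K = 1001`
equally weighted quantile points `z_k`, each carrying a disease-free
weight `w_k(t)` depleted by its own hazard `lambda_0(t) e^{b z_k}`
(all-cause mortality multiplies every weight equally and cancels in the
ratio, so it is omitted), and

$$\lambda_0(t) = \lambda_m(t)\,\frac{\sum_k w_k(t)}{\sum_k w_k(t) e^{b z_k}}.$$

A single forward pass over the yearly grid suffices because depletion at
age `t` uses only already-calibrated earlier ages. With `b = 0` the factor
is exactly 1; with negligible cumulative incidence it converges to the
lognormal-mean factor `e^{-b^2/2}`; and simulating 200,000 women from the
calibrated model reproduces `lambda_m` decade by decade within Monte-Carlo
error — all three limits are tested. The naive constant-factor variant is
kept behind `method = "naive"` for sensitivity checks. `K = 1001` makes
the quantile-discretization error of `E[e^{bZ}]` about 1e-5 at `b ≈ 0.4`,
far below every tolerance used.

Percentile curves fix `z` at standard-normal quantiles of the nominal
percentile — the cohort scores are standardized by construction — rather
than at empirical cohort quantiles; an explicit `z_values` argument covers
the empirical mode. The log hazard ratio fed to the risk model is taken
from the Cox fit. Lifetime curves run from age 20 to 80 by default:
breast-cancer incidence below 20 is negligible, so the start age hardly
matters, and 80 is where registry curves are conventionally reported; both
are arguments.

# The synthetic-data generators

The generators define the study conditions under which the package is
validated:

* **Genotypes**: biallelic dosages as two independent allele draws
  (Hardy–Weinberg), MAF uniform over a configurable range, optional planted
  missingness and low-MAF variants for QC tests. No linkage disequilibrium,
  no population structure, no genotyping-error model.
* **Weights**: Normal(0, 0.05) effect sizes — the scale of published
  per-variant breast-cancer log-odds weights — with non-palindromic allele
  pairs by default, at any SNP count (the published sets span 77–3820).
* **Rates**: incidence zero below 25, then a logistic rise with asymptote
  3.3e-3/yr, midpoint 50 and scale 8 years, approximating the Nordic female
  breast-cancer registry shape (cumulative hazard over 20–80 of ~0.10,
  i.e. a ~9–10% lifetime risk scale); mortality is Gompertz
  `2e-5 * exp(0.095 t)`, the standard adult all-cause shape.
* **Cohorts**: onset ages drawn by inverse-CDF sampling from the piecewise
  constant hazard `lambda0(t) e^{b z}`, death from the mortality table,
  entry ages truncated-Normal(30, 10, min 20), administrative censoring
  Normal(85, 8) capped at 90. Left truncation is realized by rejection —
  subjects whose outcome precedes entry are discarded, which is how a
  prevalent cohort arises; a condition-on-survival sampler is deliberately
  out of scope. Under these defaults about 10% of retained subjects are
  incident cases, echoing the ~1:7 case:control imbalance of the
  motivating cohorts. An optional `case_control_target` subsamples to an
  exact balance, but outcome-dependent subsampling biases the partial
  likelihood, so recovery tests use natural cohorts.

Because the generators satisfy the model's own assumptions exactly
(proportional hazards, independent censoring, no LD), passing recovery
tests demonstrates the estimators are correct, not that real cohorts meet
those assumptions: ascertainment through cancer-history families,
imputation noise and BRCA carriers are all outside what these simulations
emulate.

# Validation design and problem sizes

The suite pairs every estimator with an independent oracle: exhaustive
pair counting for AUC (n ≤ 12), a generic optimizer on the Bernoulli
likelihood for the logistic slope, `survival::coxph` and a brute-force
partial likelihood for the Cox fit, O(n²) enumeration for the concordance
index (n = 300), and closed forms for constant-hazard risks. Parameter
recovery simulates 100 cohorts of 8,000 with true log-HR ln(1.494) and
requires ≥90% CI coverage; decile calibration compares observed case
counts in a 20,000-subject cohort generated from the calibrated hazard
itself with the model's expected counts (the top decile carries about
twice the cases of the fifth). These sizes keep each individual check
under a few seconds while leaving Monte-Carlo error well inside the
asserted tolerances.

Bundled under `inst/extdata/` are *synthetic* registry-shaped rate tables
(`nordcan_incidence_synthetic.tsv`, `gho_mortality_synthetic.tsv`):
hand-written step functions on the scale and shape of Norwegian female
breast-cancer incidence and all-cause mortality, labelled synthetic
because they are stand-ins, not transcriptions of the registries'
published tables.

# Interfaces

The package follows the classic R modelling idiom: `cox_lt()` is a
formula+data fitting function returning a classed object with
`print`/`summary`/`coef`/`confint`/`vcov`/`logLik` methods, and
`risk_model()` returns an object with `predict` and profile/plot methods.
`run_full_analysis()` orchestrates the full chain from a config list or
YAML file with one governing seed; a thin script wrapper
(`inst/scripts/bcprs.R`) exposes the same entry point to shell users, but
the functions themselves are the primary interface — this is an analysis
package, not a command-line tool.

# Known limitations

* Single-covariate hazard models only: no clinical covariates, no
  time-varying effects, no Fine–Gray competing-risk regression (mortality
  competes only inside the absolute-risk integral).
* Dosages are hard calls 0/1/2; fractional imputation dosages are not
  modelled beyond pass-through rejection.
* The absolute-risk engine assumes the per-SD hazard ratio is constant
  across age, as the Cox model fitted it.
* Percentile risks describe the standard-normal referent; in a cohort
  whose score distribution is skewed by ascertainment the empirical-quantile
  mode should be used instead.
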