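#' Simulate biallelic genotype dosages under Hardy-Weinberg proportions
#'
#' Per-variant minor allele frequencies are drawn uniformly over
#' `maf_range`; each dosage is the sum of two independent allele draws.
#' Optionally plants variants with known low MAF and missingness (for QC
#' tests) and random missing calls.  Deterministic given `seed`.
#'
#' @param n_samples,n_variants Matrix dimensions.
#' @param maf_range MAF interval in (0, 0.5].
#' @param seed Integer seed (mandatory: generators are pure functions of
#'   their configuration and seed).
#' @param weights Optional `weight_table`; if given, variant ids and
#'   effect-orientation alleles are taken from it (the counted allele is the
#'   effect allele), so the output harmonizes 1:1.
#' @param missing_rate Fraction of calls set missing at random (default 0).
#' @param n_low_maf Number of leading variants forced to `low_maf`.
#' @param low_maf MAF for planted low-frequency variants (default 0.005).
#' @param n_high_missing_samples Number of leading samples with call missing
#'   rate `high_missing_rate`.
#' @param high_missing_rate Missing rate for planted bad samples
#'   (default 0.10).
#' @return List: `genotypes` (a `genotype_matrix`), `maf` (true values).
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5), seed,
                               weights = NULL, missing_rate = 0,
                               n_low_maf = 0L, low_maf = 0.005,
                               n_high_missing_samples = 0L,
                               high_missing_rate = 0.10) {
  stopifnot(!missing(seed), maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  if (n_low_maf > 0) maf[seq_len(n_low_maf)] <- low_maf
  dos <- matrix(stats::rbinom(n_samples * n_variants, 2L,
                              rep(maf, each = n_samples)),
                nrow = n_samples)
  if (missing_rate > 0)
    dos[stats::runif(length(dos)) < missing_rate] <- NA
  if (n_high_missing_samples > 0) {
    for (i in seq_len(n_high_missing_samples)) {
      hit <- stats::runif(n_variants) < high_missing_rate
      dos[i, hit] <- NA
    }
  }
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "weight_table"),
              nrow(weights) == n_variants)
    vids <- weights$variant_id
    alleles <- data.frame(variant_id = vids,
                          allele1 = weights$effect_allele,
                          allele2 = weights$other_allele)
  } else {
    vids <- paste0("rs", seq_len(n_variants))
    al <- random_allele_pairs(n_variants)
    alleles <- data.frame(variant_id = vids,
                          allele1 = al[, 1], allele2 = al[, 2])
  }
  gm <- genotype_matrix(dos,
                        sample_ids = sprintf("S%05d", seq_len(n_samples)),
                        variant_ids = vids, alleles = alleles)
  list(genotypes = gm, maf = maf)
}

#' Simulate a PRS weight set
#'
#' Effect sizes are Normal(0, `effect_sd`), the scale of published
#' per-variant breast-cancer log-odds weights; allele pairs avoid
#' strand-ambiguous palindromes unless requested.  Stand-in for the
#' published 77/313/2803/3820-SNP weight sets.
#'
#' @param n_variants Number of variants.
#' @param effect_sd SD of the effect sizes (default 0.05).
#' @param seed Integer seed.
#' @param allow_palindromic Allow A/T and C/G pairs (default FALSE).
#' @return A `weight_table`.
#' @export
simulate_weights <- function(n_variants, effect_sd = 0.05, seed,
                             allow_palindromic = FALSE) {
  stopifnot(!missing(seed), effect_sd >= 0)
  set.seed(seed)
  al <- random_allele_pairs(n_variants, allow_palindromic)
  weight_table(data.frame(
    variant_id = paste0("rs", seq_len(n_variants)),
    chromosome = as.character(sample(1:22, n_variants, replace = TRUE)),
    position = sort(sample.int(2.5e8, n_variants)),
    effect_allele = al[, 1], other_allele = al[, 2],
    beta = stats::rnorm(n_variants, 0, effect_sd)))
}

random_allele_pairs <- function(n, allow_palindromic = FALSE) {
  acgt <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a1 <- sample(acgt, n, replace = TRUE)
  a2 <- vapply(a1, function(a) {
    pool <- setdiff(acgt, if (allow_palindromic) a else c(a, comp[[a]]))
    sample(pool, 1)
  }, "")
  cbind(a1, unname(a2))
}

#' Synthetic registry-shaped rate tables
#'
#' Incidence: zero below `onset_min`, then a logistic rise
#' `plateau / (1 + exp(-(t - midpoint)/scale))` approximating the shape of
#' Nordic female breast-cancer registry incidence (defaults: plateau
#' 3.3e-3/yr, midpoint 50, scale 8, onset 25).  Mortality: Gompertz
#' `alpha * exp(gamma * t)` (defaults alpha 2e-5, gamma 0.095), the standard
#' adult all-cause shape.  Rates are constant within bins, evaluated at bin
#' midpoints.
#'
#' @param plateau Incidence asymptote per person-year.
#' @param midpoint,scale Logistic location and width in years.
#' @param onset_min Age below which incidence is zero.
#' @param mortality_alpha,mortality_gamma Gompertz parameters.
#' @param age_max Upper end of the modelled span (tables cover
#'   `[0, age_max)`).
#' @param bin_width Bin width in years (default 1).
#' @return List of two `rate_table`s: `incidence`, `mortality`.
#' @export
synthetic_rates <- function(plateau = 3.3e-3, midpoint = 50, scale = 8,
                            onset_min = 25, mortality_alpha = 2e-5,
                            mortality_gamma = 0.095, age_max = 90,
                            bin_width = 1L) {
  lo <- seq.int(0L, age_max - bin_width, by = bin_width)
  hi <- lo + bin_width
  mid <- (lo + hi) / 2
  inc <- ifelse(mid < onset_min, 0,
                plateau * stats::plogis((mid - midpoint) / scale))
  mort <- mortality_alpha * exp(mortality_gamma * mid)
  list(incidence = rate_table(lo, hi, inc, kind = "incidence"),
       mortality = rate_table(lo, hi, mort, kind = "mortality"))
}

#' Simulate an age-at-onset cohort under proportional hazards
#'
#' Generates a left-truncated, right-censored cohort from the model
#' `h(t, z) = lambda0(t) * exp(true_b * z)`: onset ages are drawn by
#' inverse-CDF sampling from the piecewise-constant hazard, death ages from
#' the mortality table, entry ages from a truncated normal and
#' administrative censoring ages from a normal capped at `max_age`.  A
#' sample is an (incident) case if onset precedes death, censoring and
#' `max_age`; samples whose outcome (event or end of follow-up) precedes
#' their entry age are discarded, realizing left truncation the way a
#' prevalent cohort arises.
#'
#' @param prs_z Standardized score per subject (e.g. `rnorm(n)` or scored
#'   simulated genotypes).
#' @param true_b True log hazard ratio per SD.
#' @param lambda0 `rate_table` used as the generative baseline hazard.
#' @param mortality `rate_table` of all-cause mortality (may be zero rates).
#' @param entry_age Numeric `(mean, sd, min)` of the truncated-normal entry
#'   age (default c(30, 10, 20)).
#' @param censor_age Numeric `(mean, sd)` of administrative censoring age
#'   (default c(85, 8)).
#' @param max_age Administrative end of follow-up (default 90).
#' @param seed Integer seed.
#' @param case_control_target Optional `c(n_cases, n_controls)` to subsample
#'   the realized cohort to a fixed case:control balance (note: outcome-
#'   dependent subsampling; use for cohort shaping, not unbiased hazard
#'   estimation).
#' @return A `cohort_table` with `prs_z` filled; attribute `n_discarded`
#'   counts subjects removed by truncation.
#' @export
simulate_onset_cohort <- function(prs_z, true_b, lambda0, mortality,
                                  entry_age = c(30, 10, 20),
                                  censor_age = c(85, 8),
                                  max_age = 90, seed,
                                  case_control_target = NULL) {
  stopifnot(!missing(seed), inherits(lambda0, "rate_table"),
            inherits(mortality, "rate_table"))
  set.seed(seed)
  n <- length(prs_z)

  onset <- draw_piecewise_exponential(lambda0, multiplier = exp(true_b * prs_z))
  death <- draw_piecewise_exponential(mortality, multiplier = rep(1, n))
  entry <- pmax(entry_age[3], stats::rnorm(n, entry_age[1], entry_age[2]))
  censor <- pmin(max_age, stats::rnorm(n, censor_age[1], censor_age[2]))

  end_follow <- pmin(death, censor, max_age)
  event <- onset < end_follow
  exit <- ifelse(event, onset, end_follow)

  keep <- exit > entry            # outcome after entry: observable subject
  if (!any(keep)) stop("empty cohort: all outcomes precede entry age")
  df <- data.frame(sample_id = sprintf("S%05d", seq_len(n))[keep],
                   status = ifelse(event[keep], "case", "control"),
                   entry_age = entry[keep], exit_age = exit[keep],
                   event = event[keep], prs_z = prs_z[keep])
  n_disc <- n - sum(keep)

  if (!is.null(case_control_target)) {
    cases <- which(df$event); ctrls <- which(!df$event)
    if (length(cases) < case_control_target[1] ||
        length(ctrls) < case_control_target[2])
      stop("cohort too small for requested case/control target")
    pick <- c(sample(cases, case_control_target[1]),
              sample(ctrls, case_control_target[2]))
    df <- df[sort(pick), ]
  }
  out <- cohort_table(df)
  attr(out, "n_discarded") <- n_disc
  out
}

## inverse-CDF draw of an event age from a piecewise-constant hazard,
## per-subject proportional multiplier; Inf when the hazard is exhausted
draw_piecewise_exponential <- function(rates, multiplier) {
  g <- rate_grid(rates)
  cumH <- c(0, cumsum(g$rate))
  u <- stats::rexp(length(multiplier)) / multiplier   # target baseline cum hazard
  i <- findInterval(u, cumH, left.open = FALSE)       # bin index (1-based year)
  hit <- u < cumH[length(cumH)]
  age <- rep(Inf, length(u))
  ii <- i[hit]
  age[hit] <- g$ages[ii] + (u[hit] - cumH[ii]) / g$rate[ii]
  age
}

#' Simulate standardized PRS values directly
#'
#' Standard-normal draws, the distribution a cohort-standardized PRS has by
#' construction; the alternative to scoring simulated genotypes when only
#' the downstream survival machinery is under test.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_prs <- function(n, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  stats::rnorm(n)
}
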