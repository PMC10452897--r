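#' Run the full PRS risk-stratification analysis
#'
#' Orchestrates the stages score -> discriminate -> cox -> risk -> stratify
#' as one reproducible run: genotype QC, harmonization against the weight
#' set, PRS computation and standardization, ROC AUC and OR per SD,
#' the left-truncated Cox fit of age at onset, absolute-risk calibration
#' against the incidence table, percentile risk profiles, and observed
#' decile case counts.  One seed governs the whole run; re-running with the
#' same configuration reproduces the report exactly.
#'
#' The configuration is a named list (or path to a YAML file) with either
#' file inputs
#' \preformatted{
#' weights: weights.tsv        # read_weights()
#' dosages: dosages.tsv        # read_dosage_matrix()
#' phenotypes: pheno.tsv       # read_phenotypes()
#' incidence: incidence.tsv    # read_rate_table(kind = "incidence")
#' mortality: mortality.tsv    # read_rate_table(kind = "mortality")
#' }
#' or a `simulate:` block (`n_samples`, `n_variants`, `true_b`) in which
#' case all inputs are generated by the synthetic-data module.  Optional
#' keys: `seed` (default 1), `qc` thresholds, `percentiles`, `start_age`,
#' `end_age`, `ties`.
#'
#' @param config Named list or path to a YAML config file.
#' @param outdir Optional directory; when given, intermediate TSV tables
#'   and a JSON run report are written there.
#' @return A `prs_run` report: `qc`, `harmonization`, `discrimination`,
#'   `cox`, `risk_summary` (risks at ages 50/60/70/80 per percentile),
#'   `decile_counts`, `config`, `seed`, `version`.
#' @export
run_full_analysis <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  set.seed(seed)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n <- sim$n_samples %||% 2000L
    m <- sim$n_variants %||% 100L
    true_b <- sim$true_b %||% log(1.494)
    weights <- simulate_weights(m, effect_sd = sim$effect_sd %||% 0.05,
                                seed = seed)
    geno <- simulate_genotypes(n, m, seed = seed + 1L,
                               weights = weights)$genotypes
    rates <- synthetic_rates()
    incidence <- rates$incidence; mortality <- rates$mortality
    pheno_from_scores <- function(z)
      simulate_onset_cohort(z, true_b = true_b, lambda0 = incidence,
                            mortality = mortality, seed = seed + 2L)
    phenotypes <- NULL
  } else {
    for (k in c("weights", "dosages", "phenotypes", "incidence", "mortality"))
      if (is.null(config[[k]])) stop("config is missing input '", k, "'")
    weights <- read_weights(config$weights)
    geno <- read_dosage_matrix(config$dosages)
    phenotypes <- read_phenotypes(config$phenotypes)
    incidence <- read_rate_table(config$incidence, "incidence")
    mortality <- read_rate_table(config$mortality, "mortality")
    pheno_from_scores <- NULL
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  scored <- stage("score", prs_score(
    weights, geno,
    snp_missing_max = config$qc$snp_missing_max %||% 0.02,
    maf_min = config$qc$maf_min %||% 0.02,
    sample_missing_max = config$qc$sample_missing_max %||% 0.02))
  scores <- scored$scores

  if (is.null(phenotypes)) {
    phenotypes <- stage("simulate_cohort", pheno_from_scores(scores$prs_z))
    scores <- scores[match(phenotypes$sample_id, scores$sample_id), ]
  } else {
    idx <- match(phenotypes$sample_id, scores$sample_id)
    if (anyNA(idx))
      stop("stage 'score' failed: phenotype samples absent from dosages")
    scores <- scores[idx, ]
    phenotypes$prs_raw <- scores$prs_raw
    phenotypes$prs_z <- scores$prs_z
  }

  disc <- stage("discriminate",
                discrimination(phenotypes$prs_z, phenotypes$status))
  cox <- stage("cox", fit_cox_lt_rc(phenotypes,
                                    ties = config$ties %||% "efron"))
  model <- stage("risk", risk_model(incidence, mortality,
                                    log_hr = unname(coef(cox))))
  prof <- stage("risk", risk_profiles(
    model,
    percentiles = config$percentiles %||% c(.01, .25, .50, .75, .90, .99),
    start_age = config$start_age %||% 20,
    end_age = config$end_age %||% 80))
  deciles <- stage("stratify", observed_case_counts(phenotypes, bins = 10))

  milestone <- intersect(c(50, 60, 70, 80), prof$ages)
  risk_summary <- prof$cumulative_risk[, as.character(milestone), drop = FALSE]

  report <- structure(list(
    qc = scored$qc, harmonization = scored$harmonization,
    discrimination = disc, cox = cox, risk_profile = prof,
    risk_summary = risk_summary, decile_counts = deciles,
    config = config, seed = seed,
    version = as.character(utils::packageVersion("prsrisk"))),
    class = "prs_run")

  if (!is.null(outdir)) write_run_report(report, phenotypes, scores, outdir)
  report
}

#' @export
print.prs_run <- function(x, ...) {
  cat("PRS risk-stratification run (seed ", x$seed, ")\n\n", sep = "")
  print(x$harmonization)
  cat("\n"); print(x$discrimination)
  cat("\n"); print(x$cox)
  cat("\ncumulative risk (%) by percentile at milestone ages:\n")
  print(round(100 * x$risk_summary, 2))
  cat("\nobserved cases per PRS decile:\n")
  print(x$decile_counts$n_cases)
  invisible(x)
}

write_run_report <- function(report, phenotypes, scores, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(phenotypes, file.path(outdir, "cohort_scored.tsv"))
  write_tsv_plain(as.data.frame(scores), file.path(outdir, "scores.tsv"))
  prof <- report$risk_profile
  cum <- data.frame(percentile = rep(prof$percentiles,
                                     each = length(prof$ages)),
                    age = rep(prof$ages, length(prof$percentiles)),
                    cumulative_risk = as.vector(t(prof$cumulative_risk)))
  write_tsv_plain(cum, file.path(outdir, "risk_profiles.tsv"))
  write_tsv_plain(report$decile_counts,
                  file.path(outdir, "decile_counts.tsv"))
  js <- list(
    seed = report$seed, version = report$version,
    qc = report$qc[grep("^n_", names(report$qc))],
    harmonization = report$harmonization[c("n_in_model", "n_matched",
                                           "n_flipped", "n_dropped")],
    discrimination = report$discrimination[c("auc", "or_per_sd",
                                             "or_se_log", "n_cases",
                                             "n_controls")],
    cox = list(b = unname(coef(report$cox)), se = report$cox$se,
               hr = report$cox$hr, ci95 = report$cox$ci95,
               c_index = report$cox$c_index, n_events = report$cox$n_events),
    risk_summary = as.data.frame(report$risk_summary))
  jsonlite::write_json(js, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
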