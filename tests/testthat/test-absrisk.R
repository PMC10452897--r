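const_model <- function(lam = 0.01, m = 0, b = 0, span = 100) {
  risk_model(rate_table(0, span, lam, "incidence"),
             rate_table(0, span, m, "mortality"), log_hr = b)
}

test_that("baseline calibration: identity at b = 0, lognormal-mean limit", {
  inc <- rate_table(0, 100, 0.01, "incidence")
  ch <- calibrate_baseline(inc, b = 0)
  expect_equal(ch$lambda0, rep(0.01, 100), tolerance = 1e-14)

  # negligible cumulative incidence: lambda0 -> lambda_m * exp(-b^2/2)
  tiny <- rate_table(0, 100, 1e-7, "incidence")
  ch2 <- calibrate_baseline(tiny, b = log(1.5))
  expect_equal(ch2$lambda0 / (1e-7 * exp(-log(1.5)^2 / 2)),
               rep(1, 100), tolerance = 1e-3)

  # naive variant applies exactly the E[e^{bZ}] factor everywhere
  chn <- calibrate_baseline(inc, b = log(1.5), method = "naive")
  expect_equal(chn$lambda0 / chn$lambda0[1], rep(1, 100), tolerance = 1e-14)
  # depletion makes lambda0 rise with age relative to the naive constant
  chd <- calibrate_baseline(inc, b = log(1.5))
  expect_true(all(diff(chd$lambda0) > 0))
  expect_gt(chd$lambda0[100], chn$lambda0[100])
})

test_that("calibrated model reproduces the marginal incidence in simulation", {
  rates <- synthetic_rates()
  b <- log(1.5)
  ch <- calibrate_baseline(rates$incidence, b = b)

  # simulate onset ages from the calibrated model for a standard-normal
  # population and compare age-specific incidence to lambda_m per decade
  n <- 200000
  z <- simulate_prs(n, seed = 71)
  set.seed(72)
  cumH <- c(0, cumsum(ch$lambda0))
  u <- rexp(n) / exp(b * z)
  i <- pmin(findInterval(u, cumH), length(ch$ages))
  onset <- ifelse(u < cumH[length(cumH)],
                  ch$ages[i] + (u - cumH[i]) / ch$lambda0[i],
                  Inf)
  for (dec_lo in c(30, 40, 50, 60, 70)) {
    at_risk_years <- sum(pmin(pmax(onset - dec_lo, 0), 10))
    events <- sum(onset >= dec_lo & onset < dec_lo + 10)
    obs <- events / at_risk_years
    expected <- mean(rate_at(rates$incidence, dec_lo:(dec_lo + 9)))
    se <- sqrt(events) / at_risk_years
    expect_lt(abs(obs - expected), 4 * se + 1e-6)
  }
})

test_that("absolute risk matches constant-hazard closed forms", {
  m0 <- const_model(lam = 0.01, m = 0)
  expect_equal(absolute_risk(m0, 20, 10, 0), 1 - exp(-0.1), tolerance = 1e-12)

  mm <- const_model(lam = 0.01, m = 0.01)
  expect_equal(absolute_risk(mm, 20, 10, 0), 0.5 * (1 - exp(-0.2)),
               tolerance = 1e-12)
  # long horizon approaches the cause-specific share lam/(lam+m) = 1/2
  expect_equal(absolute_risk(mm, 0, 100, 0), 0.5 * (1 - exp(-2)),
               tolerance = 1e-12)

  expect_error(absolute_risk(m0, 20, 100, 0), "grid")
  expect_error(absolute_risk(m0, -5, 10, 0), "grid")
})

test_that("risk windows are additive, monotone and bounded", {
  rates <- synthetic_rates()
  model <- risk_model(rates$incidence, rates$mortality, log_hr = log(1.494))
  for (z in c(-2, 0, 2)) {
    r_full <- absolute_risk(model, 20, 40, z)
    part <- absolute_risk(model, 20, 15, z, return_survival = TRUE)
    r_rest <- absolute_risk(model, 35, 25, z)
    expect_equal(r_full, part$risk + part$survival * r_rest,
                 tolerance = 1e-12)
  }
  # non-decreasing in tau; increasing in z at fixed window (b > 0)
  taus <- seq(5, 60, by = 5)
  r_tau <- vapply(taus, function(t) absolute_risk(model, 20, t, 0), 0)
  expect_true(all(diff(r_tau) >= 0))
  zs <- seq(-2.5, 2.5, by = 0.5)
  r_z <- absolute_risk(model, 20, 60, zs)
  expect_true(all(diff(r_z) > 0))
  # mortality only lowers risk: bounded by the pure-hazard cumulative bound
  lam_tot <- sum(model$hazard$lambda0[model$ages >= 20 & model$ages < 80])
  expect_lt(absolute_risk(model, 20, 60, 0), 1 - exp(-lam_tot) + 1e-12)
})

test_that("percentile profiles behave as the model dictates", {
  rates <- synthetic_rates()
  model <- risk_model(rates$incidence, rates$mortality, log_hr = log(1.494))
  prof <- risk_profiles(model)
  # median percentile is exactly the z = 0 curve
  expect_equal(prof$z_values[3], 0, tolerance = 1e-12)
  expect_equal(prof$cumulative_risk["p50", "80"],
               absolute_risk(model, 20, 60, 0), tolerance = 1e-12)
  # curves are non-decreasing in age and ordered in percentile everywhere
  expect_true(all(apply(prof$cumulative_risk, 1, function(r) all(diff(r) >= 0))))
  # strictly ordered in percentile once incidence has accrued
  expect_true(all(apply(prof$cumulative_risk[, as.character(30:80)], 2,
                        function(col) all(diff(col) > 0))))
  expect_true(all(prof$cumulative_risk >= 0 & prof$cumulative_risk <= 1))
  # sliding windows agree with direct evaluation
  expect_equal(unname(prof$ten_year_risk["p90", "50"]),
               absolute_risk(model, 50, 10, qnorm(0.90)), tolerance = 1e-12)
  expect_error(risk_profiles(model, percentiles = c(0, 0.5)), "percentiles")
})

test_that("observed case counts stratify and respect the null", {
  # all cases in the top bin when scores separate perfectly
  co <- cohort_table(data.frame(
    sample_id = as.character(1:100),
    status = rep(c("control", "case"), c(90, 10)),
    entry_age = 20, exit_age = 50, event = rep(c(FALSE, TRUE), c(90, 10)),
    prs_z = c(rnorm(90, -2), rnorm(10, 5))))
  counts <- observed_case_counts(co, bins = 10)
  expect_equal(counts$n_cases[10], 10)
  expect_equal(sum(counts$n_cases), 10)
  expect_equal(counts$n_total, rep(10, 10))

  # b = 0: counts flat across deciles within binomial error
  co0 <- sim_cohort(n = 6000, true_b = 0, seed = 73)
  c0 <- observed_case_counts(co0, bins = 10)
  expected <- sum(c0$n_cases) / 10
  expect_true(all(abs(c0$n_cases - expected) < 4 * sqrt(expected)))

  # percentile-edge form
  cp <- observed_case_counts(co0, bins = c(0, 0.5, 0.9, 1))
  expect_equal(sum(cp$n_cases), sum(c0$n_cases))
  expect_equal(nrow(cp), 3)
})
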