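#' Calibrate the baseline hazard to a marginal incidence curve
#'
#' Given a registry marginal incidence rate and a per-SD log hazard ratio
#' `b`, solves for the baseline hazard `lambda0(t)` such that the
#' proportional-hazards model `lambda0(t) * exp(b * Z)`, averaged over the
#' population still disease-free at age `t`, reproduces the marginal rate.
#' The referent risk-score distribution (standard normal by default) is
#' represented by `k_points` equally weighted quantile points `z_k`;
#' survival weights `w_k(t)` start at 1 and are depleted by the disease
#' hazard `lambda0(t) * exp(b * z_k)` — high-scoring subjects are removed
#' faster, so the disease-free score distribution drifts down with age
#' (susceptible depletion).  Shared all-cause mortality multiplies every
#' weight equally and cancels in the calibration ratio, so it is omitted.
#' One forward pass over the yearly grid suffices because depletion at age
#' `t` only uses already-calibrated earlier ages:
#' `lambda0(t) = lambda_m(t) * sum(w_k) / sum(w_k * exp(b * z_k))`.
#'
#' With `b = 0` this returns `lambda0 = lambda_m` exactly.  The `"naive"`
#' method ignores depletion and uses the constant factor
#' `1 / mean(exp(b * z_k))` (approximately `exp(-b^2/2)` for a normal
#' referent); it is kept for sensitivity checks.
#'
#' @param lambda_m A `rate_table` of kind `"incidence"` (marginal rates).
#' @param b Log hazard ratio per unit of the risk score.
#' @param method `"depletion"` (default) or `"naive"`.
#' @param k_points Number of quantile points representing the referent
#'   distribution (default 1001).
#' @return A `calibrated_hazard`: `ages` (yearly grid), `lambda0`, `b`,
#'   `method`, `referent` description.
#' @export
calibrate_baseline <- function(lambda_m, b, method = c("depletion", "naive"),
                               k_points = 1001L) {
  stopifnot(inherits(lambda_m, "rate_table"))
  if (!is.finite(b)) stop("b must be finite")
  method <- match.arg(method)
  g <- rate_grid(lambda_m)
  zk <- stats::qnorm((seq_len(k_points) - 0.5) / k_points)
  ebz <- exp(b * zk)
  lam0 <- numeric(length(g$ages))
  if (method == "naive") {
    lam0 <- g$rate / mean(ebz)
  } else {
    w <- rep(1, k_points)
    for (i in seq_along(g$ages)) {
      sw <- sum(w)
      swe <- sum(w * ebz)
      if (!is.finite(sw) || !is.finite(swe) || swe <= 0)
        stop("non-finite calibration weights")
      lam0[i] <- g$rate[i] * sw / swe
      w <- w * exp(-lam0[i] * ebz)
    }
  }
  structure(list(ages = g$ages, lambda0 = lam0, b = b, method = method,
                 referent = sprintf("standard normal (%d quantile points)",
                                    k_points),
                 z_points = zk),
            class = "calibrated_hazard")
}

#' @export
print.calibrated_hazard <- function(x, ...) {
  cat(sprintf("calibrated baseline hazard: ages %d-%d, b = %.4f (%s)\n",
              min(x$ages), max(x$ages) + 1L, x$b, x$method))
  invisible(x)
}

#' Absolute-risk model with competing mortality
#'
#' Bundles a calibrated baseline hazard with an all-cause mortality curve
#' into a model for the absolute risk of disease onset,
#' `R(a, a + tau) = int_a^{a+tau} lambda0(t) e^{bz}
#'   exp(-int_a^t (lambda0(u) e^{bz} + m(u)) du) dt`,
#' i.e. the probability of onset in the window given being alive and
#' disease-free at `a`, with death a competing risk.
#'
#' @param incidence A `rate_table` (kind `"incidence"`), the marginal
#'   age-specific disease incidence used to calibrate `lambda0`.
#' @param mortality A `rate_table` (kind `"mortality"`); its span must cover
#'   the incidence span.
#' @param log_hr Log hazard ratio per 1 SD of the (standardized) risk score,
#'   typically `log(coef)` from a [cox_lt()] fit — here the coefficient is
#'   already on the log scale, so pass `coef(fit)` directly.
#' @param method,k_points Passed to [calibrate_baseline()].
#' @return A `risk_model`.  Methods: [predict.risk_model()], `print`,
#'   [plot.risk_profile()] on its profiles.
#' @seealso [absolute_risk()], [risk_profiles()]
#' @export
risk_model <- function(incidence, mortality, log_hr,
                       method = c("depletion", "naive"), k_points = 1001L) {
  stopifnot(inherits(incidence, "rate_table"),
            inherits(mortality, "rate_table"))
  method <- match.arg(method)
  haz <- calibrate_baseline(incidence, b = log_hr, method = method,
                            k_points = k_points)
  span_m <- c(mortality$age_lo[1], mortality$age_hi[nrow(mortality)])
  span_i <- c(min(haz$ages), max(haz$ages) + 1L)
  if (span_m[1] > span_i[1] || span_m[2] < span_i[2])
    stop("mortality table must cover the incidence age span")
  m <- rate_at(mortality, haz$ages)
  structure(list(hazard = haz, mortality = m, ages = haz$ages,
                 log_hr = log_hr),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(paste0("absolute-risk model: ages %d-%d, HR per SD = %.3f, ",
                     "calibration = %s\n"),
              min(x$ages), max(x$ages) + 1L, exp(x$log_hr),
              x$hazard$method))
  invisible(x)
}

#' Absolute risk of onset over an age window
#'
#' Evaluates `R(a, a + tau)` for score values `z` on the model's 1-year
#' grid with exact piecewise-exponential algebra: within each year with
#' disease hazard `lam = lambda0(t) e^{bz}` and mortality `m`, the
#' contribution is `S * lam/(lam + m) * (1 - exp(-(lam + m)))`, and the
#' carried survival factor is multiplied by `exp(-(lam + m))`.  Because the
#' registry rates are step functions, this is grid-exact (no quadrature
#' error).
#'
#' @param model A `risk_model`.
#' @param a Start age (integer year on the model grid).
#' @param tau Window length in years (integer, `a + tau` within the grid).
#' @param z Risk-score values (vectorized).
#' @param return_survival If TRUE also return the all-cause (disease-free
#'   and alive) survival factor over the window.
#' @return Numeric vector of risks in `[0, 1]` (one per `z`), or a list
#'   `(risk, survival)` if `return_survival`.
#' @export
absolute_risk <- function(model, a, tau, z, return_survival = FALSE) {
  stopifnot(inherits(model, "risk_model"))
  if (tau < 0 || a %% 1 != 0 || tau %% 1 != 0)
    stop("a and tau must be whole years, tau >= 0")
  lo <- model$ages[1]; hi <- model$ages[length(model$ages)] + 1L
  if (a < lo || a + tau > hi)
    stop("window [", a, ", ", a + tau, "] outside model grid [",
         lo, ", ", hi, "]")
  idx <- which(model$ages >= a & model$ages < a + tau)
  ebz <- exp(model$log_hr * z)
  risk <- numeric(length(z))
  S <- rep(1, length(z))
  for (i in idx) {
    lam <- model$hazard$lambda0[i] * ebz
    m <- model$mortality[i]
    tot <- lam + m
    contrib <- ifelse(tot > 0, lam / tot * (1 - exp(-tot)), 0)
    risk <- risk + S * contrib
    S <- S * exp(-tot)
  }
  if (return_survival) list(risk = risk, survival = S) else risk
}

#' Predict absolute risks from a risk model
#'
#' @param object A `risk_model`.
#' @param age Start age(s).
#' @param tau Window length in years (default 10).
#' @param z Risk-score value(s); recycled against `age`.
#' @param ... Unused.
#' @return Numeric vector of risks `R(age, age + tau)`.
#' @export
predict.risk_model <- function(object, age, tau = 10, z = 0, ...) {
  k <- max(length(age), length(z))
  age <- rep_len(age, k); z <- rep_len(z, k)
  vapply(seq_len(k), function(i) absolute_risk(object, age[i], tau, z[i]),
         numeric(1))
}

#' Lifetime and 10-year risk curves by PRS percentile
#'
#' For each percentile `p` the score is fixed at the standard-normal
#' quantile `z = qnorm(p)` (the cohort scores are standardized; an
#' `empirical` mode using observed cohort quantiles is available) and two
#' families of curves are computed: the cumulative risk from `start_age`,
#' `R(start_age, a)` for `a` up to `end_age`, and the sliding `tau`-year
#' risk `R(a, a + tau)`.
#'
#' @param model A `risk_model`.
#' @param percentiles Probabilities in (0, 1); default the conventional
#'   1st/25th/50th/75th/90th/99th.
#' @param start_age,end_age Curve span (defaults 20 and 80; incidence below
#'   20 is negligible for breast cancer so the start hardly matters).
#' @param tau Sliding-window length (default 10 years).
#' @param z_values Optional explicit score values overriding `qnorm(p)`
#'   (e.g. empirical cohort quantiles).
#' @return A `risk_profile`: `percentiles`, `z_values`, `ages`,
#'   `cumulative_risk` (percentile x age matrix of `R(start_age, a)`) and
#'   `ten_year_risk` (percentile x age matrix of `R(a, a + tau)` for
#'   `a <= end_age - tau`).
#' @export
risk_profiles <- function(model, percentiles = c(.01, .25, .50, .75, .90, .99),
                          start_age = 20, end_age = 80, tau = 10,
                          z_values = NULL) {
  stopifnot(inherits(model, "risk_model"))
  if (any(percentiles <= 0 | percentiles >= 1))
    stop("percentiles must lie strictly in (0, 1)")
  z <- if (is.null(z_values)) stats::qnorm(percentiles) else z_values
  stopifnot(length(z) == length(percentiles))

  ages <- start_age:end_age
  cum <- matrix(0, length(z), length(ages),
                dimnames = list(sprintf("p%02d", round(100 * percentiles)),
                                ages))
  # incremental accumulation: one pass per percentile over the grid
  for (j in seq_along(z)) {
    ebz <- exp(model$log_hr * z[j])
    S <- 1; acc <- 0
    cum[j, 1] <- 0
    for (a in ages[-length(ages)]) {
      lam <- model$hazard$lambda0[match(a, model$ages)] * ebz
      m <- model$mortality[match(a, model$ages)]
      tot <- lam + m
      acc <- acc + if (tot > 0) S * lam / tot * (1 - exp(-tot)) else 0
      S <- S * exp(-tot)
      cum[j, match(a + 1L, ages)] <- acc
    }
  }
  slide_ages <- start_age:(end_age - tau)
  ten <- matrix(0, length(z), length(slide_ages),
                dimnames = list(rownames(cum), slide_ages))
  for (j in seq_along(z))
    for (k in seq_along(slide_ages))
      ten[j, k] <- absolute_risk(model, slide_ages[k], tau, z[j])

  structure(list(percentiles = percentiles, z_values = z, ages = ages,
                 cumulative_risk = cum, ten_year_risk = ten,
                 start_age = start_age, end_age = end_age, tau = tau),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("risk profile: ages %d-%d, percentiles %s\n",
              x$start_age, x$end_age,
              paste(100 * x$percentiles, collapse = "/")))
  cat(sprintf("cumulative risk at %d (%%):\n", x$end_age))
  print(round(100 * x$cumulative_risk[, ncol(x$cumulative_risk)], 2))
  invisible(x)
}

#' Plot risk curves by PRS percentile
#'
#' @param x A `risk_profile`.
#' @param which `"cumulative"` or `"ten_year"`.
#' @param ... Passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.risk_profile <- function(x, which = c("cumulative", "ten_year"), ...) {
  which <- match.arg(which)
  if (which == "cumulative") {
    m <- x$cumulative_risk; xa <- x$ages
    ylab <- sprintf("cumulative risk from age %d", x$start_age)
  } else {
    m <- x$ten_year_risk; xa <- as.integer(colnames(x$ten_year_risk))
    ylab <- sprintf("%d-year risk", x$tau)
  }
  graphics::matplot(xa, t(100 * m), type = "l", lty = 1, lwd = 2,
                    xlab = "age (years)", ylab = paste(ylab, "(%)"), ...)
  graphics::legend("topleft", legend = paste0(100 * x$percentiles, "th"),
                   col = seq_along(x$percentiles), lty = 1, lwd = 2,
                   bty = "n", title = "PRS percentile")
  invisible(x)
}

#' Observed case counts per PRS bin
#'
#' Bins the pooled cohort on empirical quantiles of the standardized score
#' and counts cases per bin — the observed counterpart of the model's
#' percentile risk stratification.
#'
#' @param cohort A `cohort_table`.
#' @param score Score per sample; defaults to `cohort$prs_z`.
#' @param bins Either a single integer (number of equal-probability bins,
#'   default 10 for deciles) or a vector of probability edges in `[0, 1]`.
#' @return Data frame: `bin`, `lo`, `hi` (score edges), `n_cases`,
#'   `n_total`.
#' @export
observed_case_counts <- function(cohort, score = cohort$prs_z, bins = 10) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(score) || anyNA(score)) stop("a complete score vector is required")
  probs <- if (length(bins) == 1L) seq(0, 1, length.out = bins + 1L) else bins
  stopifnot(length(probs) >= 2L, !is.unsorted(probs),
            probs[1] == 0, probs[length(probs)] == 1)
  edges <- stats::quantile(score, probs, names = FALSE, type = 7)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  g <- cut(score, edges, labels = FALSE, include.lowest = TRUE)
  is_case <- cohort$status == "case"
  data.frame(bin = seq_len(length(probs) - 1L),
             p_lo = probs[-length(probs)], p_hi = probs[-1],
             n_cases = as.integer(tapply(is_case, factor(g, levels = seq_len(length(probs) - 1L)), sum, default = 0L)),
             n_total = as.integer(tabulate(g, nbins = length(probs) - 1L)))
}
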