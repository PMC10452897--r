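#' Left-truncated right-censored Cox proportional hazards fit
#'
#' Fits the proportional hazards model `h(t, x) = lambda0(t) * exp(b * x)` on
#' the age time scale by maximizing the partial likelihood in which the risk
#' set at an event age `t` comprises the samples with
#' `entry_age < t <= exit_age` — subjects enter observation at their
#' (left-truncation) entry age and leave at diagnosis or last follow-up.
#' Tied event ages use the Efron correction by default (ages recorded in
#' whole years make ties common); Breslow is available.  The score's
#' Harrell concordance index over the same truncation-adjusted comparable
#' pairs is attached.
#'
#' This is the machinery behind per-SD hazard ratios of a standardized PRS:
#' with `x` the standardized score, `exp(b)` is the hazard ratio per 1 SD.
#'
#' @param formula `survival::Surv(entry, exit, event) ~ x` with a single
#'   numeric predictor (counting-process response).
#' @param data Data frame holding the variables.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_lt` object: `coefficients` (named `b`), `se`, `hr`,
#'   `ci95`, `loglik` (null, final), `c_index`, `c_se`, `n`, `n_events`,
#'   `iter`.  Methods: `print`, `summary`, `coef`, `vcov`, `confint`,
#'   `logLik`.
#' @examples
#' d <- data.frame(entry = c(0, 0, 0, 0), exit = c(2, 3, 4, 5),
#'                 event = c(1, 1, 0, 1), x = c(1.2, 0.1, -0.5, -1))
#' cox_lt(survival::Surv(entry, exit, event) ~ x, d)
#' @export
cox_lt <- function(formula, data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "counting")
    stop("response must be survival::Surv(entry, exit, event)")
  if (ncol(mf) != 2L || !is.numeric(mf[[2L]]))
    stop("exactly one numeric predictor is supported")
  fit <- coxlt_fit(entry = y[, 1], exit = y[, 2], event = y[, 3] == 1,
                   x = mf[[2L]], ties = ties)
  fit$call <- match.call()
  fit$predictor <- names(mf)[2L]
  fit
}

#' Fit the age-at-onset Cox model on a scored cohort
#'
#' Thin wrapper around [cox_lt()] for a `cohort_table` carrying standardized
#' scores: age at onset on `prs_z`, left-truncated at `entry_age`,
#' right-censored at `exit_age`.
#'
#' @param cohort A `cohort_table` with `prs_z` set for all samples.
#' @param ties Tie correction, see [cox_lt()].
#' @return A `cox_lt` fit (hazard ratio per 1 SD of PRS).
#' @export
fit_cox_lt_rc <- function(cohort, ties = c("efron", "breslow")) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!"prs_z" %in% names(cohort) || anyNA(cohort$prs_z))
    stop("cohort must carry prs_z for every sample")
  ties <- match.arg(ties)
  fit <- coxlt_fit(cohort$entry_age, cohort$exit_age, cohort$event,
                   cohort$prs_z, ties = ties)
  fit$call <- match.call()
  fit$predictor <- "prs_z"
  fit
}

coxlt_fit <- function(entry, exit, event, x, ties = "efron") {
  stopifnot(length(entry) == length(exit), length(exit) == length(event),
            length(event) == length(x))
  if (anyNA(entry) || anyNA(exit) || anyNA(event) || anyNA(x))
    stop("missing values in survival data")
  if (any(exit <= entry)) stop("exit time must exceed entry time")
  event <- as.logical(event)
  n_events <- sum(event)
  if (n_events < 2L) stop("at least 2 events are required")

  xc <- x - mean(x)                      # centering: invariant for b, stable
  se_exit <- sort(exit); o_exit <- order(exit)
  se_entry <- sort(entry); o_entry <- order(entry)
  ut <- sort(unique(exit[event]))
  grp <- match(exit[event], ut)
  d <- tabulate(grp, nbins = length(ut))
  x_ev <- xc[event]
  sum_x_ev <- sum(x_ev)
  # position of each event time in the sorted exit / entry vectors
  pos_exit <- findInterval(ut, se_exit, left.open = TRUE)   # exits < t
  pos_entry <- findInterval(ut, se_entry, left.open = TRUE) # entries < t
  rep_j <- rep.int(seq_along(ut), d)
  frac <- if (ties == "efron") (sequence(d) - 1) / rep.int(d, d) else
    rep.int(0, n_events)

  lik_parts <- function(b) {
    w <- exp(b * xc)
    tw <- w[o_exit]; cw <- cumsum(tw); tot <- cw[length(cw)]
    cwx <- cumsum(tw * xc[o_exit]); cwx2 <- cumsum(tw * xc[o_exit]^2)
    ew <- w[o_entry]; ce <- cumsum(ew)
    cex <- cumsum(ew * xc[o_entry]); cex2 <- cumsum(ew * xc[o_entry]^2)
    at0 <- function(v, i) ifelse(i == 0L, 0, v[pmax(i, 1L)])
    S0 <- (tot - at0(cw, pos_exit)) - (sum(ew) - at0(ce, pos_entry))
    S1 <- (cwx[length(cwx)] - at0(cwx, pos_exit)) -
      (cex[length(cex)] - at0(cex, pos_entry))
    S2 <- (cwx2[length(cwx2)] - at0(cwx2, pos_exit)) -
      (cex2[length(cex2)] - at0(cex2, pos_entry))
    w_ev <- w[event]
    s0d <- rowsum(w_ev, grp)[, 1]
    s1d <- rowsum(w_ev * x_ev, grp)[, 1]
    s2d <- rowsum(w_ev * x_ev^2, grp)[, 1]
    D <- S0[rep_j] - frac * s0d[rep_j]
    N1 <- S1[rep_j] - frac * s1d[rep_j]
    N2 <- S2[rep_j] - frac * s2d[rep_j]
    if (any(!is.finite(D)) || any(D <= 0))
      stop("non-finite partial likelihood")
    r1 <- N1 / D
    list(ll = b * sum_x_ev - sum(log(D)),
         grad = sum_x_ev - sum(r1),
         hess = -sum(N2 / D - r1^2))
  }

  b <- 0
  p <- lik_parts(b)
  ll0 <- p$ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- -p$grad / p$hess
    if (!is.finite(step)) stop("non-finite likelihood: cannot fit")
    b_new <- b + step
    p_new <- lik_parts(b_new)
    halvings <- 0L
    while (p_new$ll < p$ll && halvings < 30L) {    # step-halving safeguard
      step <- step / 2
      b_new <- b + step
      p_new <- lik_parts(b_new)
      halvings <- halvings + 1L
    }
    converged <- abs(p_new$ll - p$ll) < 1e-9
    b <- b_new; p <- p_new
    if (converged || iter >= 50L) break
  }
  se <- sqrt(-1 / p$hess)
  conc <- harrell_c_core(entry, exit, event, x)

  structure(list(
    coefficients = c(b = b),
    se = se,
    hr = exp(b),
    ci95 = exp(b + c(-1.96, 1.96) * se),
    loglik = c(null = ll0, final = p$ll),
    c_index = conc$c_index, c_se = conc$c_se,
    n = length(x), n_events = n_events,
    iter = iter, converged = converged, ties = ties),
    class = "cox_lt")
}

#' @export
print.cox_lt <- function(x, ...) {
  cat("Left-truncated right-censored Cox fit (", x$ties, " ties)\n", sep = "")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  b = %.4f (se %.4f), HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$coefficients, x$se, x$hr, x$ci95[1], x$ci95[2]))
  cat(sprintf("  concordance = %.4f (se %.4f)\n", x$c_index, x$c_se))
  invisible(x)
}

#' @export
summary.cox_lt <- function(object, ...) {
  z <- object$coefficients / object$se
  out <- list(fit = object,
              table = data.frame(
                coef = unname(object$coefficients), se = object$se,
                z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
                HR = object$hr, lo95 = object$ci95[1], hi95 = object$ci95[2],
                row.names = object$predictor %||% "x"))
  class(out) <- "summary.cox_lt"
  out
}

#' @export
print.summary.cox_lt <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.cox_lt <- function(object, ...) object$coefficients

#' @export
vcov.cox_lt <- function(object, ...) {
  matrix(object$se^2, 1, 1,
         dimnames = list(names(object$coefficients),
                         names(object$coefficients)))
}

#' @export
confint.cox_lt <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  b <- unname(object$coefficients)
  matrix(b + c(-q, q) * object$se, 1, 2,
         dimnames = list(names(object$coefficients),
                         paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                " %")))
}

#' @export
logLik.cox_lt <- function(object, ...) {
  structure(object$loglik[["final"]], df = 1L, class = "logLik")
}

#' Harrell's concordance index under left truncation
#'
#' The probability, over comparable subject pairs, that the subject with the
#' earlier event carries the higher score.  A pair `(i, j)` is comparable
#' when `i` has an event at `t_i` and `j` is under observation at that age:
#' `entry_j < t_i <= exit_j` (and `j != i`).  Score ties get half credit.
#' The standard error is a per-event cluster (Noether-type U-statistic)
#' estimator.
#'
#' @param cohort A `cohort_table`.
#' @param score Numeric risk score per sample; defaults to `cohort$prs_z`.
#' @return List: `c_index`, `c_se`, `n_pairs`.
#' @export
harrell_c <- function(cohort, score = cohort$prs_z) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(score) || anyNA(score)) stop("a complete score vector is required")
  harrell_c_core(cohort$entry_age, cohort$exit_age, cohort$event, score)
}

harrell_c_core <- function(entry, exit, event, score) {
  ev <- which(event)
  if (!length(ev)) stop("no events: concordance undefined")
  conc <- num <- numeric(length(ev))
  for (k in seq_along(ev)) {
    i <- ev[k]
    t_i <- exit[i]
    cmp <- entry < t_i & t_i <= exit
    cmp[i] <- FALSE
    m <- sum(cmp)
    if (m == 0) next
    s <- score[cmp]
    conc[k] <- sum(score[i] > s) + 0.5 * sum(score[i] == s)
    num[k] <- m
  }
  M <- sum(num)
  if (M == 0) stop("no comparable pairs: concordance undefined")
  C <- sum(conc) / M
  ci <- ifelse(num > 0, conc / pmax(num, 1), 0)
  c_se <- sqrt(sum((num * (ci - C))^2)) / M
  list(c_index = C, c_se = c_se, n_pairs = M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
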