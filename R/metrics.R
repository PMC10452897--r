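#' Area under the ROC curve of a score against case status
#'
#' Computed as the Mann-Whitney probability
#' `P(z_case > z_control) + 0.5 * P(tie)`, via midranks; this equals the
#' trapezoidal area under the empirical ROC curve.  Ties get half credit.
#'
#' @param z Numeric scores.
#' @param status `"case"`/`"control"`, or logical/0-1 with TRUE = case.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(z, status) {
  y <- as_case(status)
  stopifnot(length(z) == length(y), !anyNA(z), !anyNA(y))
  n1 <- as.numeric(sum(y)); n0 <- as.numeric(sum(!y))
  if (n1 == 0 || n0 == 0)
    stop("AUC needs at least one case and one control")
  r <- rank(z, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Odds ratio per standard deviation of PRS
#'
#' Maximum-likelihood logistic regression of case status on the standardized
#' score, fitted by iteratively reweighted least squares (Newton scoring on
#' the Bernoulli log-likelihood); the odds ratio per 1 SD is `exp(beta)` and
#' its standard error (log scale) comes from the observed information.
#' No covariates are included.
#'
#' @param z Standardized scores.
#' @param status Case labels as in [roc_auc()].
#' @param tol Convergence tolerance on the coefficient update (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return List: `or_per_sd`, `beta` (log odds ratio), `or_se_log`,
#'   `ci95` (Wald, OR scale), `n_iter`.
#' @export
logistic_or_per_sd <- function(z, status, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(as_case(status))
  stopifnot(length(z) == length(y), !anyNA(z))
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  X <- cbind(1, z)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (all(w < 1e-12))
      stop("complete separation: logistic likelihood has no finite maximum")
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    delta <- solve(info, score)
    beta <- beta + drop(delta)
    if (max(abs(beta)) > 30)
      stop("complete separation: logistic likelihood has no finite maximum")
    if (max(abs(delta)) < tol) break
  }
  if (it == max_iter && max(abs(delta)) >= tol)
    warning("logistic IRLS did not converge in ", max_iter, " iterations")
  se <- unname(sqrt(solve(info)[2, 2]))
  b <- unname(beta[2])
  list(or_per_sd = exp(b), beta = b, or_se_log = se,
       ci95 = exp(b + c(-1, 1) * 1.96 * se), n_iter = it)
}

#' Discrimination summary of a standardized PRS
#'
#' Bundles ROC AUC and logistic OR per SD with class sizes, the per-model
#' performance summary reported for PRS comparisons.
#'
#' @inheritParams roc_auc
#' @return A `discrimination` object: `auc`, `or_per_sd`, `or_se_log`,
#'   `or_ci95`, `n_cases`, `n_controls`.
#' @export
discrimination <- function(z, status) {
  y <- as_case(status)
  fit <- logistic_or_per_sd(z, y)
  structure(list(auc = roc_auc(z, y),
                 or_per_sd = fit$or_per_sd,
                 or_se_log = fit$or_se_log,
                 or_ci95 = fit$ci95,
                 n_cases = sum(y), n_controls = sum(!y)),
            class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  cat(sprintf("PRS discrimination (%d cases / %d controls)\n",
              x$n_cases, x$n_controls))
  cat(sprintf("  AUC       %.4f\n", x$auc))
  cat(sprintf("  OR per SD %.3f (SE log %.3f, 95%% CI %.3f-%.3f)\n",
              x$or_per_sd, x$or_se_log, x$or_ci95[1], x$or_ci95[2]))
  invisible(x)
}

as_case <- function(status) {
  if (is.character(status) || is.factor(status)) {
    s <- as.character(status)
    if (!all(s %in% c("case", "control")))
      stop("status must be 'case'/'control' or logical/0-1")
    s == "case"
  } else as.logical(status)
}
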