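#' Genotype quality-control filter
#'
#' Applies the standard chip-QC filters in a fixed order: (1) variants with a
#' missing-call rate above `snp_missing_max`, (2) variants with minor allele
#' frequency below `maf_min` (computed from non-missing dosages on the
#' remaining variants), (3) samples with a missing rate above
#' `sample_missing_max` over the remaining variants.  Defaults are the usual
#' 2% / 2% / 2%.
#'
#' @param genotypes A `genotype_matrix`.
#' @param snp_missing_max Maximum per-variant missing fraction (exclusive).
#' @param maf_min Minimum minor allele frequency (exclusive lower bound:
#'   variants with MAF < `maf_min` are removed).
#' @param sample_missing_max Maximum per-sample missing fraction (exclusive).
#' @return A list with `genotypes` (the filtered `genotype_matrix`) and
#'   `report`: counts and ids removed at each stage.
#' @export
qc_filter <- function(genotypes, snp_missing_max = 0.02, maf_min = 0.02,
                      sample_missing_max = 0.02) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  stopifnot(snp_missing_max >= 0, snp_missing_max <= 1,
            maf_min >= 0, maf_min <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1)
  d <- genotypes$dosage

  snp_miss <- colMeans(is.na(d))
  drop_miss <- snp_miss > snp_missing_max
  d2 <- d[, !drop_miss, drop = FALSE]

  p <- colMeans(d2, na.rm = TRUE) / 2        # counted-allele frequency
  maf <- pmin(p, 1 - p)
  drop_maf <- is.na(maf) | maf < maf_min
  d3 <- d2[, !drop_maf, drop = FALSE]

  samp_miss <- rowMeans(is.na(d3))
  drop_samp <- samp_miss > sample_missing_max
  d4 <- d3[!drop_samp, , drop = FALSE]

  if (ncol(d4) == 0L || nrow(d4) == 0L)
    stop("no variants or samples remain after QC filtering")

  keep_var <- colnames(d4)
  al <- genotypes$alleles[match(keep_var, genotypes$alleles$variant_id), ]
  out <- genotype_matrix(d4, sample_ids = rownames(d4),
                         variant_ids = keep_var, alleles = al)
  report <- list(
    n_variants_in = ncol(d), n_samples_in = nrow(d),
    n_snp_removed_missing = sum(drop_miss),
    snp_removed_missing = colnames(d)[drop_miss],
    n_snp_removed_maf = sum(drop_maf),
    snp_removed_maf = colnames(d2)[drop_maf],
    n_samples_removed = sum(drop_samp),
    samples_removed = rownames(d3)[drop_samp],
    n_variants_out = ncol(d4), n_samples_out = nrow(d4))
  list(genotypes = out, report = report)
}

#' Harmonize genotype dosages against a PRS weight table
#'
#' Matches model variants to genotyped variants by id and reorients dosages
#' to count the model's effect allele.  For each model variant:
#' \itemize{
#'   \item absent from the genotypes, or alleles undeclared: dropped;
#'   \item strand-ambiguous palindromic pair (A/T or C/G): dropped
#'     unconditionally — strand cannot be resolved from alleles alone;
#'   \item declared alleles equal the model pair in the same orientation:
#'     matched as-is;
#'   \item declared alleles equal the model pair in swapped orientation:
#'     dosage replaced by `2 - dosage`, counted as flipped;
#'   \item any other allele pair: dropped as an allele-set mismatch.
#' }
#' Drops are reported, never fatal; published weight sets routinely lose
#' variants to the target chip this way.
#'
#' @param weights A `weight_table`.
#' @param genotypes A `genotype_matrix`.
#' @param unknown_alleles Policy for genotype variants whose counted allele
#'   was not declared: `"drop"` (default, conservative) or
#'   `"assume_matched"` (trust that the file already counts the effect
#'   allele).
#' @return A `harmonized_prs` object: `dosage` (samples x matched variants,
#'   effect-allele counts), `beta` (aligned effect sizes) and `report`
#'   (a `harmonization_report`: `n_in_model`, `n_matched`, `n_flipped`,
#'   `n_dropped`, `dropped` with reasons).
#' @export
harmonize <- function(weights, genotypes,
                      unknown_alleles = c("drop", "assume_matched")) {
  stopifnot(inherits(weights, "weight_table"),
            inherits(genotypes, "genotype_matrix"))
  unknown_alleles <- match.arg(unknown_alleles)

  idx <- match(weights$variant_id, genotypes$variant_ids)
  ea <- weights$effect_allele; oa <- weights$other_allele
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  palindromic <- oa == comp[ea]

  status <- rep("absent", nrow(weights))
  present <- !is.na(idx)
  g1 <- genotypes$alleles$allele1[idx]
  g2 <- genotypes$alleles$allele2[idx]

  unknown <- present & is.na(g1)
  same <- present & !is.na(g1) & g1 == ea & g2 == oa
  swapped <- present & !is.na(g1) & g1 == oa & g2 == ea

  status[present] <- "mismatch"
  status[unknown] <- if (unknown_alleles == "drop") "no_alleles" else "matched"
  status[same] <- "matched"
  status[swapped] <- "flipped"
  status[palindromic] <- ifelse(present[palindromic], "palindromic", "absent")

  keep <- status %in% c("matched", "flipped")
  dmat <- genotypes$dosage[, idx[keep], drop = FALSE]
  flip <- status[keep] == "flipped"
  if (any(flip)) dmat[, flip] <- 2 - dmat[, flip, drop = FALSE]
  colnames(dmat) <- weights$variant_id[keep]

  dropped <- data.frame(variant_id = weights$variant_id[!keep],
                        reason = status[!keep])
  report <- structure(list(
    n_in_model = nrow(weights),
    n_matched = sum(keep),
    n_flipped = sum(flip),
    n_dropped = sum(!keep),
    dropped = dropped), class = "harmonization_report")
  stopifnot(report$n_matched + report$n_dropped == report$n_in_model)

  structure(list(dosage = dmat,
                 beta = weights$beta[keep],
                 variant_id = weights$variant_id[keep],
                 sample_ids = genotypes$sample_ids,
                 report = report),
            class = "harmonized_prs")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("harmonization:", x$n_matched, "of", x$n_in_model,
      "model variants used (", x$n_flipped, "flipped,",
      x$n_dropped, "dropped )\n")
  if (x$n_dropped)
    print(table(x$dropped$reason))
  invisible(x)
}

#' Compute raw polygenic risk scores
#'
#' The additive score of sample `j` is `sum_i a_ij * beta_i` over the
#' harmonized model variants, where `a_ij` is the effect-allele dosage.
#' Missing dosages are replaced by the variant's cohort mean dosage before
#' summation (the usual scoring-software default), which leaves the cohort
#' mean score equal to the complete-case mean.  No clumping, pruning or
#' p-value thresholding is applied: the weight set is used as published.
#'
#' @param harmonized A `harmonized_prs` from [harmonize()].
#' @return A `score_set`: data.frame `sample_id`, `prs_raw` (with `prs_z`
#'   unset until [standardize()]).
#' @export
compute_prs <- function(harmonized) {
  stopifnot(inherits(harmonized, "harmonized_prs"))
  d <- harmonized$dosage
  if (ncol(d) == 0L) stop("zero matched variants: cannot compute a PRS")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    if (anyNA(mu))
      stop("variant(s) with no observed dosages: ",
           paste(colnames(d)[is.na(mu)], collapse = ", "))
    na_idx <- which(is.na(d))
    d[na_idx] <- mu[((na_idx - 1L) %/% nrow(d)) + 1L]
  }
  raw <- drop(d %*% harmonized$beta)
  structure(data.frame(sample_id = harmonized$sample_ids,
                       prs_raw = raw, prs_z = NA_real_),
            class = c("score_set", "data.frame"),
            cohort_mean = NA_real_, cohort_sd = NA_real_)
}

#' Standardize polygenic risk scores over the cohort
#'
#' Z-scores the raw PRS over the entire scored cohort (cases and controls
#' pooled): subtract the cohort mean, divide by the cohort standard
#' deviation.  The population (divide-by-N) SD convention is used and pinned
#' by tests.  Idempotent to numerical tolerance.
#'
#' @param scores A `score_set` with `prs_raw` filled.
#' @return The `score_set` with `prs_z`, and `cohort_mean` / `cohort_sd`
#'   attributes recording the transformation.
#' @export
standardize <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  x <- scores$prs_raw
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  if (!is.finite(sdv) || sdv == 0)
    stop("constant PRS: standard deviation is zero")
  scores$prs_z <- (x - mu) / sdv
  attr(scores, "cohort_mean") <- mu
  attr(scores, "cohort_sd") <- sdv
  scores
}

#' Score a cohort end-to-end
#'
#' Convenience wrapper: QC filter, harmonize, compute and standardize the
#' PRS in one call.
#'
#' @param weights A `weight_table`.
#' @param genotypes A `genotype_matrix`.
#' @param qc Apply [qc_filter()] first? Default TRUE.
#' @param ... QC thresholds passed to [qc_filter()].
#' @return A list: `scores` (standardized `score_set`), `harmonization`
#'   (report), `qc` (report or NULL).
#' @export
prs_score <- function(weights, genotypes, qc = TRUE, ...) {
  qc_rep <- NULL
  if (qc) {
    f <- qc_filter(genotypes, ...)
    genotypes <- f$genotypes
    qc_rep <- f$report
  }
  h <- harmonize(weights, genotypes)
  s <- standardize(compute_prs(h))
  list(scores = s, harmonization = h$report, qc = qc_rep)
}
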