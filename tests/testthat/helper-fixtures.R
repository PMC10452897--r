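# Small in-code fixtures and independent brute-force oracles shared by the
# test files.  Oracles are deliberately naive (double loops, generic
# optimizers) and never call the implementation paths they check.

tiny_weights <- function() {
  weight_table(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chromosome = c("1", "2", "3"),
    position = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(0.1, -0.2, 0.05)))
}

tiny_genotypes <- function(dosage = rbind(c(2, 1, 0), c(0, 2, 1)),
                           flip = logical(3)) {
  w <- tiny_weights()
  a1 <- ifelse(flip, w$other_allele, w$effect_allele)
  a2 <- ifelse(flip, w$effect_allele, w$other_allele)
  genotype_matrix(dosage,
                  sample_ids = paste0("S", seq_len(nrow(dosage))),
                  variant_ids = w$variant_id,
                  alleles = data.frame(variant_id = w$variant_id,
                                       allele1 = a1, allele2 = a2))
}

write_tsv_tmp <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# exhaustive all-pairs AUC with half credit for ties
auc_bruteforce <- function(z, y) {
  zc <- z[y]; z0 <- z[!y]
  tot <- 0
  for (a in zc) for (b in z0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(zc) * length(z0))
}

# partial log-likelihood by definition (risk set scan per event), Efron ties
coxpl_bruteforce <- function(b, entry, exit, event, x) {
  ll <- 0
  for (t in sort(unique(exit[event]))) {
    tied <- which(event & exit == t)
    rs <- which(entry < t & t <= exit)
    d <- length(tied)
    s0 <- sum(exp(b * x[rs]))
    s0d <- sum(exp(b * x[tied]))
    ll <- ll + b * sum(x[tied]) -
      sum(log(s0 - ((seq_len(d) - 1) / d) * s0d))
  }
  ll
}

# concordance by O(n^2) pair enumeration under the truncation-aware rule
cindex_bruteforce <- function(entry, exit, event, score) {
  num <- den <- 0
  n <- length(exit)
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (entry[j] < exit[i] && exit[i] <= exit[j]) {
        den <- den + 1
        num <- num + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
      }
    }
  }
  num / den
}

# standard small test cohort: standard-normal PRS, synthetic rates
sim_cohort <- function(n = 2000, true_b = log(1.494), seed = 1,
                       rates = synthetic_rates()) {
  z <- simulate_prs(n, seed = seed)
  simulate_onset_cohort(z, true_b = true_b, lambda0 = rates$incidence,
                        mortality = rates$mortality, seed = seed + 1000L)
}
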