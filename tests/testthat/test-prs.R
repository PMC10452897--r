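test_that("QC removes variants and samples at the stated thresholds, in order", {
  # one SNP missing in 3% of samples at a 2% threshold is removed
  g <- simulate_genotypes(100, 5, maf_range = c(0.3, 0.5), seed = 2)$genotypes
  g$dosage[1:3, 2] <- NA
  out <- qc_filter(g)
  expect_false("rs2" %in% out$genotypes$variant_ids)
  expect_equal(out$report$snp_removed_missing, "rs2")

  # clean common variants pass through untouched
  clean <- simulate_genotypes(100, 5, maf_range = c(0.3, 0.5), seed = 2)$genotypes
  out2 <- qc_filter(clean)
  expect_equal(out2$genotypes$dosage, clean$dosage)

  # planted low-MAF variants and high-missing samples are exactly the removals
  big <- simulate_genotypes(1000, 500, maf_range = c(0.1, 0.5), seed = 7,
                            n_low_maf = 10, low_maf = 0.002,
                            n_high_missing_samples = 5,
                            high_missing_rate = 0.10)$genotypes
  res <- qc_filter(big)
  expect_setequal(res$report$snp_removed_maf, paste0("rs", 1:10))
  expect_equal(res$report$n_snp_removed_missing, 0)
  expect_setequal(res$report$samples_removed, sprintf("S%05d", 1:5))
  expect_equal(res$report$n_variants_out, 490)
  expect_equal(res$report$n_samples_out, 995)

  expect_error(qc_filter(big, maf_min = 1), "no variants")
})

test_that("harmonization matches, flips and drops by the allele rules", {
  w <- tiny_weights()                      # A/G, C/T, G/A
  g <- tiny_genotypes(flip = c(FALSE, FALSE, TRUE))
  h <- harmonize(w, g)
  expect_equal(h$report$n_matched, 3)
  expect_equal(h$report$n_flipped, 1)
  # flipped variant rs3: dosage 0,1 -> 2,1
  expect_equal(unname(h$dosage[, "rs3"]), c(2, 1))
  expect_equal(unname(h$dosage[, "rs1"]), c(2, 0))

  # palindromic model variant dropped unconditionally
  wp <- weight_table(data.frame(variant_id = "rs1", chromosome = "1",
                                position = 1L, effect_allele = "A",
                                other_allele = "T", beta = 0.1))
  gp <- genotype_matrix(matrix(c(1, 2), 2, 1), sample_ids = c("a", "b"),
                        variant_ids = "rs1",
                        alleles = data.frame(variant_id = "rs1",
                                             allele1 = "A", allele2 = "T"))
  hp <- harmonize(wp, gp)
  expect_equal(hp$report$n_dropped, 1)
  expect_equal(hp$report$dropped$reason, "palindromic")

  # allele-set mismatch and absent variants drop; report balances
  g2 <- tiny_genotypes()
  g2$alleles$allele2[2] <- "G"             # C/G pair no longer matches C/T
  h2 <- harmonize(w, g2)
  expect_equal(h2$report$n_matched + h2$report$n_dropped, h2$report$n_in_model)
  expect_true("rs2" %in% h2$report$dropped$variant_id)
})

test_that("PRS is the effect-allele-weighted dosage sum", {
  w <- weight_table(data.frame(variant_id = c("rs1", "rs2"),
                               chromosome = "1", position = 1:2,
                               effect_allele = c("A", "C"),
                               other_allele = c("G", "T"),
                               beta = c(0.1, -0.2)))
  g <- genotype_matrix(matrix(c(2, 1), 1, 2, byrow = TRUE),
                       sample_ids = "s1", variant_ids = c("rs1", "rs2"),
                       alleles = data.frame(variant_id = c("rs1", "rs2"),
                                            allele1 = c("A", "C"),
                                            allele2 = c("G", "T")))
  s <- compute_prs(harmonize(w, g))
  expect_equal(s$prs_raw, 0.1 * 2 - 0.2 * 1)

  zero <- g; zero$dosage[] <- 0
  expect_equal(compute_prs(harmonize(w, zero))$prs_raw, 0)

  # matches an independently coded double-loop sum
  ww <- simulate_weights(50, seed = 21)
  gg <- simulate_genotypes(100, 50, seed = 22, weights = ww)$genotypes
  s2 <- compute_prs(harmonize(ww, gg))
  manual <- numeric(100)
  for (j in 1:100) for (i in 1:50)
    manual[j] <- manual[j] + gg$dosage[j, i] * ww$beta[i]
  expect_equal(s2$prs_raw, manual)

  empty <- harmonize(ww, gg)
  empty$dosage <- empty$dosage[, 0, drop = FALSE]
  expect_error(compute_prs(empty), "zero matched")
})

test_that("standardization uses the population-SD convention and is idempotent", {
  s <- structure(data.frame(sample_id = letters[1:3], prs_raw = c(1, 2, 3),
                            prs_z = NA_real_),
                 class = c("score_set", "data.frame"))
  z <- standardize(s)
  expect_equal(z$prs_z, c(-1, 0, 1) / sqrt(2/3), tolerance = 1e-12)
  expect_equal(z$prs_z[3], 1.2247449, tolerance = 1e-6)

  z2 <- z; z2$prs_raw <- z$prs_z
  expect_equal(standardize(z2)$prs_z, z$prs_z, tolerance = 1e-12)

  big <- structure(data.frame(sample_id = as.character(1:500),
                              prs_raw = rnorm(500, 5, 3), prs_z = NA_real_),
                   class = c("score_set", "data.frame"))
  zb <- standardize(big)
  expect_equal(mean(zb$prs_z), 0, tolerance = 1e-12)
  expect_equal(mean(zb$prs_z^2), 1, tolerance = 1e-12)

  s$prs_raw <- rep(4, 3)
  expect_error(standardize(s), "constant")
})

test_that("scoring is linear in beta and z-invariant to orientation flips", {
  ww <- simulate_weights(40, seed = 31)
  gg <- simulate_genotypes(200, 40, seed = 32, weights = ww)$genotypes

  s1 <- compute_prs(harmonize(ww, gg))
  w2 <- ww; w2$beta <- 2 * ww$beta
  s2 <- compute_prs(harmonize(w2, gg))
  expect_equal(s2$prs_raw, 2 * s1$prs_raw, tolerance = 1e-12)

  # re-expressing the file so every variant counts the other allele
  # (declared pair swapped, dosage complemented) must leave scores unchanged
  gf <- gg
  gf$alleles[, c("allele1", "allele2")] <- gf$alleles[, c("allele2", "allele1")]
  gf$dosage <- 2 - gf$dosage
  sf <- compute_prs(harmonize(ww, gf))
  expect_equal(sf$prs_raw, s1$prs_raw, tolerance = 1e-12)
  # and with the dosages left untouched the flip report says so
  hf <- harmonize(ww, gf)
  expect_equal(hf$report$n_flipped, hf$report$n_matched)
  expect_equal(standardize(sf)$prs_z, standardize(s1)$prs_z,
               tolerance = 1e-12)
})

test_that("mean imputation preserves the cohort mean raw score", {
  ww <- simulate_weights(30, seed = 41)
  gg <- simulate_genotypes(300, 30, seed = 42, weights = ww)$genotypes
  h_full <- harmonize(ww, gg)
  full_mean <- mean(compute_prs(h_full)$prs_raw)

  gm <- gg
  set.seed(43)
  gm$dosage[runif(length(gm$dosage)) < 0.1] <- NA
  h_miss <- harmonize(ww, gm)
  # cohort mean with per-variant mean imputation equals the mean computed
  # from per-variant observed means on the same variants
  imp_mean <- mean(compute_prs(h_miss)$prs_raw)
  expected <- sum(colMeans(gm$dosage, na.rm = TRUE) * ww$beta)
  expect_equal(imp_mean, expected, tolerance = 1e-12)
})
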