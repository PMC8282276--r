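test_that("latent biological age reduces to chronological age without variability", {
  cfg <- cohort_config(n_samples = 40, n_age_genes = 20, n_null_genes = 20,
                       targets_per_mirna = 2, decoys_per_mirna = 2,
                       n_null_mirna = 5, aging_rate_sd = 0,
                       bio_age_noise_sd = 0, seed = 3)
  sim <- generate_cohort(cfg)
  expect_equal(unname(sim$truth$latent_bio_age),
               sim$samples$chronological_age)
})

test_that("planted structure matches the configured roles", {
  fx <- default_cohort()
  roles <- fx$truth$mirna_roles
  expect_identical(sum(roles == "up"), 14L)
  expect_identical(sum(roles == "down"), 6L)

  # senescence-like gene tracks latent biological age positively
  rho <- cor(fx$genes$values["CDKN2A", ], fx$truth$latent_bio_age,
             method = "spearman")
  expect_gt(rho, 0)

  # with aging-rate variability, CA and bio-age diverge but stay positive
  rho_ca <- cor(fx$ca, fx$truth$latent_bio_age[names(fx$ca)],
                method = "spearman")
  expect_gt(rho_ca, 0)
  expect_lt(rho_ca, 1)

  # every true edge references existing features
  expect_true(all(fx$truth$true_edges$mirna_id %in% feature_ids(fx$mirnas)))
  expect_true(all(fx$truth$true_edges$gene_id %in% feature_ids(fx$genes)))
})

test_that("generation is deterministic under the seed", {
  cfg <- cohort_config(n_samples = 30, n_age_genes = 10, n_null_genes = 10,
                       targets_per_mirna = 1, decoys_per_mirna = 1,
                       n_null_mirna = 4, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$genes$values, b$genes$values)
  expect_identical(a$mirnas$values, b$mirnas$values)
  expect_identical(a$truth$latent_bio_age, b$truth$latent_bio_age)
  expect_identical(generate_target_predictions(a$truth),
                   generate_target_predictions(b$truth))
})

test_that("target predictions contain the true edges plus the decoy count", {
  fx <- default_cohort()
  pred <- generate_target_predictions(fx$truth)
  te <- paste(fx$truth$true_edges$mirna_id, fx$truth$true_edges$gene_id)
  expect_true(all(te %in% paste(pred$mirna_id, pred$gene_id)))
  n_planted <- sum(fx$truth$mirna_roles != "null")
  expect_identical(nrow(pred),
                   n_planted * (fx$cfg$targets_per_mirna +
                                  fx$cfg$decoys_per_mirna))

  cfg0 <- cohort_config(n_samples = 30, n_age_genes = 10, n_null_genes = 10,
                        targets_per_mirna = 3, decoys_per_mirna = 0,
                        n_null_mirna = 4, seed = 5)
  sim0 <- generate_cohort(cfg0)
  pred0 <- generate_target_predictions(sim0$truth)
  expect_identical(pred0$gene_id, sim0$truth$true_edges$gene_id)
})

test_that("fibrosis phenotype is monotone in bio-age when noiseless, bounded always", {
  fx <- default_cohort()
  fib0 <- generate_fibrosis_phenotype(fx$truth, slope = 0.5, noise_sd = 0,
                                      intercept = 0, seed = 1)
  expect_equal(cor(fib0, fx$truth$latent_bio_age, method = "spearman"), 1)

  fib <- generate_fibrosis_phenotype(fx$truth, slope = 2, noise_sd = 30,
                                     seed = 2)
  expect_true(all(fib >= 0 & fib <= 100))
})

test_that("a slope-free phenotype is rarely called age-associated", {
  fx <- default_cohort()
  b <- fx$truth$latent_bio_age
  p <- vapply(1:100, function(s) {
    fib <- generate_fibrosis_phenotype(fx$truth, slope = 0, noise_sd = 5,
                                       intercept = 20, seed = 1000 + s)
    suppressWarnings(cor.test(fib, b, method = "spearman")$p.value)
  }, numeric(1))
  # null calibration: ~5% of seeds significant, allow binomial slack
  expect_lte(mean(p < 0.05), 0.12)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_samples = -1), "counts")
  expect_error(cohort_config(age_range = c(70, 20)), "increasing")
  expect_error(cohort_config(nb_dispersion = 0), "dispersion")
  expect_error(cohort_config(n_mirna_up = 0, n_mirna_down = 0,
                             targets_per_mirna = 2), "planted miRNA")
  expect_error(cohort_config(decoys_per_mirna = 50, n_null_genes = 10),
               "null-gene pool")
})

test_that("null features are rarely age-associated across seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- cohort_config(n_samples = 50, n_age_genes = 0, n_null_genes = 40,
                         n_mirna_up = 1, n_mirna_down = 0, n_null_mirna = 0,
                         targets_per_mirna = 0, decoys_per_mirna = 0,
                         seed = 7000 + s)
    sim <- generate_cohort(cfg)
    g <- normalize_expression(sim$genes)
    b <- sim$truth$latent_bio_age
    nulls <- names(sim$truth$gene_roles)[sim$truth$gene_roles == "null"]
    p <- apply(g$values[nulls, ], 1, function(v)
      suppressWarnings(cor.test(v, b, method = "spearman")$p.value))
    sum(p.adjust(p, "BH") <= 0.05)
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.05 + 0.10)  # binomial tolerance over 50 seeds
})
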