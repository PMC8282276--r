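test_that("single-gene marker is a plain projection", {
  m <- toy_matrix(matrix(c(1, 2, 3), 1, 3), features = "CDKN2A")
  mk <- cdkn2a_marker(m)
  expect_equal(unname(as.numeric(mk)), c(1, 2, 3))
  expect_identical(names(mk), c("s1", "s2", "s3"))
  expect_error(cdkn2a_marker(m, "P16"), "P16")
})

test_that("senescence marker tracks bio-age better than shuffled ages", {
  fx <- default_cohort()
  b <- fx$truth$latent_bio_age[names(fx$cdkn2a)]
  set.seed(1)
  rho <- abs(cor(fx$cdkn2a, b, method = "spearman"))
  rho_shuf <- abs(cor(fx$cdkn2a, sample(b), method = "spearman"))
  expect_gt(rho, rho_shuf)
})

test_that("noiseless calibrations are fitted and inverted exactly", {
  ages <- c(25, 30, 40, 55, 60, 70)
  nm <- sprintf("s%d", seq_along(ages))
  ca <- age_marker(stats::setNames(ages, nm), "CA")
  slopes <- seq(1, 2.1, by = 0.1)   # 12 genes, all exact lines x = 5 + b*CA
  vals <- t(vapply(slopes, function(b) 5 + b * ages, numeric(length(ages))))
  m <- toy_matrix(vals, samples = nm)
  model <- fit_appage(m, ca)
  expect_equal(nrow(model$genes), 12L)
  expect_equal(model$genes$beta0, rep(5, 12))
  expect_equal(model$genes$beta1, slopes)
  expect_equal(model$genes$sigma, rep(1e-6, 12))  # floored

  app <- compute_appage(model, m)
  expect_equal(unname(as.numeric(app)), ages, tolerance = 1e-8)

  # a one-gene evaluation at age 40 inverts to exactly 40
  model1 <- model; model1$genes <- model$genes[1, ]
  x40 <- toy_matrix(matrix(5 + slopes[1] * 40, 1, 1), features = "g1",
                    samples = "new")
  expect_equal(unname(as.numeric(compute_appage(model1, x40))), 40)
})

test_that("pure-noise matrices yield no age genes at FDR 0.05", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(50 * 30), 50, 30)
    m <- toy_matrix(vals)
    ca <- age_marker(stats::setNames(runif(30, 20, 70), sample_ids(m)), "CA")
    inherits(try(fit_appage(m, ca), silent = TRUE), "try-error")
  }, logical(1))
  expect_gte(mean(errs), 0.9)
})

test_that("the calibration screen recovers planted age genes", {
  fx <- default_cohort()
  model <- fit_appage(fx$genes, fx$ca)
  planted <- names(fx$truth$gene_roles)[
    fx$truth$gene_roles %in% c("age_up", "age_down")]
  expect_gte(mean(planted %in% model$genes$gene_id), 0.9)
})

test_that("AppAge is invariant to a common positive rescaling of the calibrations", {
  fx <- default_cohort()
  model <- fit_appage(fx$genes, fx$ca)
  app <- compute_appage(model, fx$genes)
  scaled <- model
  # scaling (beta1, residual scale) jointly cancels in the weighted inversion
  # only when intercepts move consistently; scale sigma alone: weights cancel
  scaled$genes$sigma <- model$genes$sigma * 3.7
  expect_equal(as.numeric(compute_appage(scaled, fx$genes)),
               as.numeric(app), tolerance = 1e-10)
})

test_that("decade bins follow the printed right-closed intervals", {
  nm <- c("a", "b", "c", "d")
  ca <- age_marker(stats::setNames(c(30, 31, 20, 70), nm), "CA")
  bins <- bin_samples(ca, "decades")
  expect_identical(bins$bin, c("20-30", "31-40", "20-30", "61-70"))

  cdk <- age_marker(stats::setNames(c(1, 2, 3, 4), nm), "CDKN2A")
  expect_error(bin_samples(cdk, "decades"), "years")
})

test_that("quintile bins are balanced, deterministic and order-equivariant", {
  vals <- stats::setNames(1:10, sprintf("s%02d", 1:10))
  bins <- bin_samples(age_marker(vals, "CDKN2A"), "fifths")
  expect_identical(bins$sample_id[bins$bin == "P20"], c("s01", "s02"))
  expect_identical(bins$sample_id[bins$bin == "P100"], c("s09", "s10"))

  fx <- default_cohort()
  sizes <- table(fx$bins$bin)
  expect_true(all(sizes %in% c(26, 27)))

  # permuting sample order leaves the assignment unchanged
  perm <- sample(length(fx$cdkn2a))
  shuffled <- age_marker(stats::setNames(as.numeric(fx$cdkn2a)[perm],
                                         names(fx$cdkn2a)[perm]), "CDKN2A")
  b2 <- bin_samples(shuffled, "fifths")
  merged <- merge(fx$bins, b2, by = "sample_id")
  expect_identical(merged$bin.x, merged$bin.y)
})

test_that("marker correlations match the rank formula and handle edge cases", {
  nm <- sprintf("s%d", 1:5)
  a <- age_marker(stats::setNames(c(3, 1, 4, 1.5, 9), nm), "CA")
  b <- age_marker(stats::setNames(c(2, 7, 1, 8, 3), nm), "CDKN2A")
  out <- marker_correlations(list(a, b))
  # no ties: Spearman rho = 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(as.numeric(a)) - rank(as.numeric(b))
  expect_equal(out$rho, 1 - 6 * sum(d^2) / (5 * 24))

  self <- marker_correlations(list(a, a))
  expect_equal(self$rho, 1)
  neg <- age_marker(stats::setNames(-as.numeric(a), nm), "AppAge")
  expect_equal(marker_correlations(list(a, neg))$rho, -1)

  const <- age_marker(stats::setNames(rep(2, 5), nm), "AppAge")
  expect_true(is.na(marker_correlations(list(a, const))$rho))
})
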