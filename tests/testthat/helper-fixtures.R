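# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# The default-condition synthetic cohort (132 donors), normalized, with
# markers and fifths ready; used wherever a test needs realistic structure.
default_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    cfg <- cohort_config(seed = 42)
    sim <- generate_cohort(cfg)
    genes <- normalize_expression(sim$genes)
    mirnas <- normalize_expression(sim$mirnas)
    ca <- ca_marker(sim$samples)
    cdk <- cdkn2a_marker(genes)
    .fixture_cache$cohort <- list(
      cfg = cfg, sim = sim, truth = sim$truth,
      genes = genes, mirnas = mirnas,
      ca = ca, cdkn2a = cdk,
      bins = bin_samples(cdk, "fifths"))
  }
  .fixture_cache$cohort
}

# Small matrix builder for toy tests.
toy_matrix <- function(values, features = NULL, samples = NULL,
                       units = "log2") {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (is.null(features)) features <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  expression_matrix(values, units = units)
}

# Independent grid-search oracle for AppAge: minimizes the weighted
# calibration SSE by direct evaluation on an age grid (coarse pass over
# [0, 120], then a fine pass at 0.001-year resolution around the optimum).
grid_appage_oracle <- function(model, mat) {
  g <- model$genes
  w <- 1 / g$sigma^2
  vals <- mat$values[g$gene_id, , drop = FALSE]
  sse <- function(a_vec, x) {
    vapply(a_vec, function(a)
      sum(w * (x - g$beta0 - g$beta1 * a)^2), numeric(1))
  }
  vapply(seq_len(ncol(vals)), function(i) {
    x <- vals[, i]
    coarse <- seq(0, 120, by = 0.1)
    a0 <- coarse[which.min(sse(coarse, x))]
    fine <- seq(a0 - 0.2, a0 + 0.2, by = 0.001)
    fine[which.min(sse(fine, x))]
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits,
# mirroring the exact-test convention (doubled smaller tail, capped at 1).
enumerate_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(u_all >= u_obs)
  else 2 * mean(u_all <= u_obs)
  list(u = u_obs, p = min(p, 1))
}

# Reference Benjamini-Hochberg step-up, written independently of p.adjust.
reference_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  cummin_rev <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q[o] <- pmin(cummin_rev, 1)
  q
}
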