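# Independent running-sum oracle: literal step-by-step walk down the list.
oracle_es <- function(scores, set, weight_p) {
  ord <- order(scores, decreasing = TRUE)
  feats <- names(scores)[ord]
  s <- scores[ord]
  hits <- feats %in% set
  nr <- sum(abs(s[hits])^weight_p)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hits[i]) abs(s[i])^weight_p / nr
    else -1 / (length(s) - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

toy_scores <- stats::setNames(c(5, 4, 3, 2.5, 2, 1, 0.5, -1, -2, -4),
                              sprintf("f%02d", 1:10))

test_that("ES matches a hand-traced running sum on a toy list", {
  set <- c("f01", "f03", "f09")
  for (w in c(0, 1, 2)) {
    res <- suppressWarnings(
      preranked_gsea(toy_scores, list(s = set), n_perm = 50, weight_p = w,
                     min_size = 1, seed = 1))
    expect_equal(res$es, oracle_es(toy_scores, set, w))
  }
})

test_that("a top-1 singleton set at weight 0 scores ES = 1", {
  sets <- list(top = "f01")
  res <- suppressWarnings(
    preranked_gsea(toy_scores, sets, n_perm = 20, weight_p = 0,
                   min_size = 1, seed = 1))
  expect_equal(res$es, 1)
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  scores <- stats::setNames(rnorm(60), sprintf("g%02d", 1:60))
  for (i in 1:5) {
    set <- sample(names(scores), 8)
    mine <- suppressWarnings(
      preranked_gsea(scores, list(s = set), n_perm = 10, weight_p = 1,
                     min_size = 1, seed = 1)$es)
    sorted <- sort(scores, decreasing = TRUE)
    ref <- fgsea::calcGseaStat(sorted, which(names(sorted) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("null enrichment scores are centred for symmetric scores", {
  set.seed(42)
  scores <- stats::setNames(c(rnorm(50, 2), -rnorm(50, 2)),
                            sprintf("g%03d", 1:100))
  set <- sample(names(scores), 50)
  res <- suppressWarnings(
    preranked_gsea(scores, list(s = set), n_perm = 500, weight_p = 1,
                   min_size = 1, seed = 7))
  # a random half-list set on a symmetric ranking is unenriched
  expect_lt(abs(res$es), 0.25)
  expect_gt(res$p, 0.05)
})

test_that("weight-0 ES is rank-based: monotone-invariant, reversal-negated", {
  set.seed(43)
  scores <- stats::setNames(sort(rnorm(40), decreasing = TRUE),
                            sprintf("g%02d", 1:40))
  set <- sample(names(scores), 6)
  es <- function(s) suppressWarnings(
    preranked_gsea(s, list(x = set), n_perm = 10, weight_p = 0,
                   min_size = 1, seed = 1)$es)
  base <- es(scores)
  # strictly monotone transform preserves ranks, hence the ES
  expect_equal(es(exp(scores / 2)), base)
  # reversing the ranking flips the walk
  expect_equal(es(stats::setNames(-scores, names(scores))), -base)
})

test_that("undersized and whole-list sets are skipped with a warning", {
  expect_warning(
    out <- preranked_gsea(toy_scores, list(tiny = "f01"), n_perm = 10,
                          min_size = 5, seed = 1),
    "fewer than")
  expect_identical(nrow(out), 0L)
  expect_error(preranked_gsea(stats::setNames(1:3, c("a", "a", "b")),
                              list(s = "a")), "uniquely named")
})

test_that("planted cardiac sets enrich on the synthetic cohort ranking", {
  fx <- default_cohort()
  de <- de_genes(fx$genes, fx$bins, "P20", "P100")
  sets <- generate_cardiac_sets(fx$truth, seed = 2)
  res <- suppressWarnings(
    preranked_gsea(gsea_ranking(de), sets, n_perm = 200, seed = 3))
  expect_true(all(c("cardiac_set_01", "null_control_set") %in% res$set_id))
  # mirror targets are age-responsive, so cardiac sets out-score the control
  expect_gt(max(abs(res$es[grepl("cardiac", res$set_id)])),
            abs(res$es[res$set_id == "null_control_set"]))
})
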