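test_that("BIO-AGEmiRNA calls recover the planted split with directions", {
  fx <- default_cohort()
  bam <- identify_bioage_mirnas(fx$mirnas, fx$cdkn2a, fx$bins)
  roles <- fx$truth$mirna_roles
  planted <- names(roles)[roles != "null"]
  recall <- mean(planted %in% bam$mirna_id)
  precision <- mean(bam$mirna_id %in% planted)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # planted directions are recovered for every true positive
  hits <- bam[bam$mirna_id %in% planted, ]
  expect_true(all(hits$direction == roles[hits$mirna_id]))
  # direction always matches the sign of the CDKN2A correlation
  expect_true(all((bam$direction == "up") == (bam$rho_cdkn2a > 0)))
})

test_that("bins from a different marker are refused", {
  fx <- default_cohort()
  ca_bins <- bin_samples(fx$ca, "fifths")
  expect_error(identify_bioage_mirnas(fx$mirnas, fx$cdkn2a, ca_bins),
               "fifths of the supplied")
})

test_that("mirror targets satisfy every filter invariant", {
  fx <- default_cohort()
  bam <- identify_bioage_mirnas(fx$mirnas, fx$cdkn2a, fx$bins)
  pred <- generate_target_predictions(fx$truth)
  mt <- select_mirror_targets(pred, fx$genes, fx$mirnas, bam,
                              fx$cdkn2a, fx$bins)
  expect_gt(nrow(mt), 0)
  # gene direction opposite its miRNA's
  mdir <- bam$direction[match(mt$mirna_id, bam$mirna_id)]
  expect_true(all(ifelse(mdir == "up", "down", "up") == mt$gene_direction))
  # anti-correlation with the miRNA
  expect_true(all(mt$rho_gene_mirna < 0))
  # every retained pair was predicted
  expect_true(all(paste(mt$mirna_id, mt$gene_id) %in%
                    paste(pred$mirna_id, pred$gene_id)))

  # recovery against the planted edges
  te <- paste(fx$truth$true_edges$mirna_id, fx$truth$true_edges$gene_id)
  kept <- paste(mt$mirna_id, mt$gene_id)
  expect_gte(mean(te %in% kept), 0.85)
  expect_lte(mean(!(kept %in% te)), 0.10)
})

test_that("removing a miRNA's predicted targets removes its table rows", {
  fx <- default_cohort()
  bam <- identify_bioage_mirnas(fx$mirnas, fx$cdkn2a, fx$bins)
  pred <- generate_target_predictions(fx$truth)
  drop_mir <- bam$mirna_id[1]
  pred2 <- pred[pred$mirna_id != drop_mir, ]
  mt2 <- select_mirror_targets(pred2, fx$genes, fx$mirnas, bam,
                               fx$cdkn2a, fx$bins)
  expect_false(drop_mir %in% mt2$mirna_id)
})

test_that("filters are individually toggleable", {
  fx <- default_cohort()
  bam <- identify_bioage_mirnas(fx$mirnas, fx$cdkn2a, fx$bins)
  pred <- generate_target_predictions(fx$truth)
  all3 <- select_mirror_targets(pred, fx$genes, fx$mirnas, bam,
                                fx$cdkn2a, fx$bins)
  anti <- select_mirror_targets(pred, fx$genes, fx$mirnas, bam,
                                fx$cdkn2a, fx$bins,
                                filters = "anticorrelation")
  expect_gte(nrow(anti), nrow(all3))
})

test_that("network construction ranks, restricts and reports coverage", {
  mirnas <- structure(
    data.frame(mirna_id = c("m1", "m2"), direction = c("up", "down"),
               rho_cdkn2a = c(0.9, -0.4), q_de = 0.01, q_corr = 0.01),
    class = c("BioAgeMiRNA", "data.frame"))
  tab <- structure(
    data.frame(mirna_id = c("m1", "m1", "m1", "m1", "m2", "m2"),
               gene_id = c("g1", "g2", "g3", "g4", "g1", "g5")),
    class = c("MirrorTargetTable", "data.frame"))
  sets <- structure(list(cardiac = c("g1", "g2", "g3", "g4")),
                    class = "GeneSetCollection")

  net <- build_network(tab, sets, mirnas)
  expect_identical(sort(unique(net$edges$gene_id)), c("g1", "g2", "g3", "g4"))
  expect_equal(unname(net$coverage["m1"]), 1.0)  # m1 targets all 4

  # top_k = 1 keeps one miRNA per direction; both survive here
  net1 <- build_network(tab, sets, mirnas, top_k = 1)
  expect_setequal(unique(net1$edges$mirna_id), c("m1", "m2"))

  # an up-only top_k ranking drops the weaker up-miRNA
  mirnas2 <- mirnas; mirnas2$direction <- c("up", "up")
  net2 <- build_network(tab, sets, mirnas2, top_k = 1)
  expect_identical(unique(net2$edges$mirna_id), "m1")

  empty_sets <- structure(list(cardiac = c("zz1", "zz2")),
                          class = "GeneSetCollection")
  expect_warning(net0 <- build_network(tab, empty_sets, mirnas),
                 "empty network")
  expect_identical(nrow(net0$edges), 0L)
})
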