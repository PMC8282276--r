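#' Generate synthetic cardiac gene-set annotation
#'
#' Builds a small synthetic gene-set collection over a generated cohort's
#' gene universe, for exercising enrichment and network stages: each
#' "cardiac" set mixes planted mirror-target genes with null genes, plus one
#' purely null control set. This is a synthetic stand-in annotation, not a
#' curated ontology.
#'
#' @param truth `SyntheticTruth` from [generate_cohort()].
#' @param n_sets Number of cardiac sets (default 3).
#' @param genes_per_set Set size (default 30).
#' @param target_fraction Fraction of each cardiac set drawn from mirror
#'   targets (default 0.5, capped by availability).
#' @param seed Integer seed.
#' @return A `GeneSetCollection` (see [read_gmt()]).
#' @export
generate_cardiac_sets <- function(truth, n_sets = 3, genes_per_set = 30,
                                  target_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(seed)
  targets <- names(truth$gene_roles)[truth$gene_roles == "mirror_target"]
  nulls <- names(truth$gene_roles)[truth$gene_roles == "null"]
  sets <- list()
  for (k in seq_len(n_sets)) {
    n_t <- min(round(target_fraction * genes_per_set), length(targets))
    members <- c(sample(targets, n_t),
                 sample(nulls, genes_per_set - n_t))
    attr(members, "description") <- "synthetic cardiac set"
    sets[[sprintf("cardiac_set_%02d", k)]] <- members
  }
  ctrl <- sample(nulls, min(genes_per_set, length(nulls)))
  attr(ctrl, "description") <- "synthetic null control set"
  sets[["null_control_set"]] <- ctrl
  structure(sets, class = "GeneSetCollection")
}

#' Pipeline configuration
#'
#' Reads (or validates) the staged-analysis configuration. The file is YAML
#' with sections: `outdir`, `seed`, `thresholds` (`q`, default 0.05),
#' `simulate` (either `enabled: true` with optional [cohort_config()]
#' overrides, fibrosis/image/panel settings, or `enabled: false`), `paths`
#' (expression/miRNA/metadata/gene-set/prediction/fibrosis/image inputs when
#' not simulating), and `stages` (logical toggles `fibrosis`, `gsea`,
#' `mirna`, `spm`). Every referenced path must exist and every threshold lie
#' in (0, 1) at validation time.
#'
#' @param config A file path to a YAML config, or a list with the same
#'   structure.
#' @return Validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(outdir = "lvbioage_out", seed = 1L,
                   thresholds = list(q = 0.05),
                   simulate = list(enabled = TRUE),
                   paths = list(),
                   stages = list(fibrosis = TRUE, gsea = TRUE,
                                 mirna = TRUE, spm = TRUE),
                   gsea = list(n_perm = 500, weight_p = 1, min_size = 5))
  cfg <- utils::modifyList(defaults, config)
  q <- cfg$thresholds$q
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stop("thresholds$q must lie in (0, 1)")
  sim <- isTRUE(cfg$simulate$enabled)
  if (!sim) {
    need <- c("genes", "metadata")
    if (isTRUE(cfg$stages$mirna)) need <- c(need, "mirnas", "predictions")
    if (isTRUE(cfg$stages$gsea)) need <- c(need, "gene_sets")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop("simulation disabled but paths missing: ",
           paste(miss, collapse = ", "))
  }
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(cfg, class = c("PipelineConfig", "list"))
}

pipeline_stage_plan <- function(cfg) {
  plan <- c(if (isTRUE(cfg$simulate$enabled)) "simulate",
            "normalize", "markers", "structure",
            if (isTRUE(cfg$stages$fibrosis)) "fibrosis",
            "de",
            if (isTRUE(cfg$stages$gsea)) "gsea",
            if (isTRUE(cfg$stages$mirna)) "mirna",
            if (isTRUE(cfg$stages$spm)) "spm")
  plan
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the staged biological-age analysis pipeline
#'
#' Chains the package's modules into the full workflow: (optional)
#' simulation, normalization, age markers (CA, CDKN2A, AppAge),
#' whole-transcriptome split with marker-overlap statistics, fibrosis
#' correlations, young-vs-old differential expression for all three
#' markers with DEG overlaps and pre-ranked GSEA, the BIO-AGEmiRNA /
#' mirror-target / network pipeline, and SPM tissue specificity. Every
#' output is a TSV under `outdir`, and a manifest records each file with
#' its MD5 plus the config hash; identical configs and seeds reproduce
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()] (list or YAML path).
#' @param dry_run If `TRUE`, only validate and print the stage plan; no
#'   files are written.
#' @return Invisibly, the run manifest: list with `outputs` (data frame
#'   `file`, `md5`), `config_hash`, `seed`, `stages`. Dry runs return the
#'   stage plan.
#' @export
run_pipeline <- function(config = list(), dry_run = FALSE) {
  cfg <- pipeline_config(config)
  plan <- pipeline_stage_plan(cfg)
  if (dry_run) {
    message("dry run; stage plan: ", paste(plan, collapse = " -> "))
    return(invisible(plan))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- "init"
  result <- tryCatch({
    q_thr <- cfg$thresholds$q
    fibrosis_values <- NULL
    panel <- NULL
    predictions <- NULL
    gene_sets <- NULL
    truth <- NULL

    if (isTRUE(cfg$simulate$enabled)) {
      stage <- "simulate"
      log_stage(stage, "generating synthetic cohort")
      cc_args <- cfg$simulate[setdiff(names(cfg$simulate),
                                      c("enabled", "fibrosis", "panel"))]
      cc_args$seed <- cfg$seed
      cohort <- do.call(cohort_config, cc_args)
      sim <- generate_cohort(cohort)
      truth <- sim$truth
      genes_counts <- sim$genes; mirnas_counts <- sim$mirnas
      samples <- sim$samples
      predictions <- generate_target_predictions(truth, cohort)
      fib_cfg <- cfg$simulate$fibrosis
      fibrosis_values <- do.call(generate_fibrosis_phenotype,
                                 c(list(truth = truth,
                                        seed = cfg$seed + 2L),
                                   fib_cfg))
      gene_sets <- generate_cardiac_sets(truth, seed = cfg$seed + 3L)
      panel <- do.call(generate_tissue_panel,
                       c(list(seed = cfg$seed + 4L), cfg$simulate$panel))
      write_expression(genes_counts, file.path(cfg$outdir, "genes_counts.gct"))
      write_expression(mirnas_counts, file.path(cfg$outdir, "mirna_counts.gct"))
      outputs <- c(outputs, file.path(cfg$outdir, c("genes_counts.gct",
                                                    "mirna_counts.gct")))
      emit(samples, "samples.tsv")
      emit(predictions, "target_predictions.tsv")
      emit(data.frame(sample_id = names(truth$latent_bio_age),
                      latent_bio_age = unname(truth$latent_bio_age),
                      fibrosis_percent = unname(fibrosis_values)),
           "synthetic_truth.tsv")
    } else {
      stage <- "load"
      log_stage(stage, "reading inputs")
      genes_counts <- read_expression(cfg$paths$genes)
      samples <- sample_table(utils::read.delim(cfg$paths$metadata,
                                                stringsAsFactors = FALSE))
      mirnas_counts <- if (!is.null(cfg$paths$mirnas))
        read_expression(cfg$paths$mirnas)
      if (!is.null(cfg$paths$predictions))
        predictions <- read_target_map(cfg$paths$predictions)
      if (!is.null(cfg$paths$gene_sets))
        gene_sets <- read_gmt(cfg$paths$gene_sets)
      if (!is.null(cfg$paths$fibrosis)) {
        fib <- utils::read.delim(cfg$paths$fibrosis, stringsAsFactors = FALSE)
        fibrosis_values <- stats::setNames(fib[[2]], fib[[1]])
      }
      if (!is.null(cfg$paths$panel)) {
        panel <- utils::read.delim(cfg$paths$panel, stringsAsFactors = FALSE)
        class(panel) <- unique(c("TissuePanel", class(panel)))
      }
    }

    stage <- "normalize"
    log_stage(stage, "CPM + log2")
    genes <- normalize_expression(genes_counts)
    mirnas <- if (!is.null(mirnas_counts)) normalize_expression(mirnas_counts)

    stage <- "markers"
    ca <- ca_marker(samples)
    cdk <- cdkn2a_marker(genes)
    model <- fit_appage(genes, ca, q_threshold = q_thr)
    appage <- compute_appage(model, genes)
    log_stage(stage, sprintf("AppAge model on %d genes", nrow(model$genes)))
    emit(model$genes, "appage_model.tsv")
    emit(data.frame(sample_id = names(ca), CA = as.numeric(ca),
                    CDKN2A = as.numeric(cdk[names(ca)]),
                    AppAge = as.numeric(appage[names(ca)])),
         "age_markers.tsv")
    emit(marker_correlations(list(ca, cdk, appage)), "marker_correlations.tsv")

    stage <- "structure"
    split <- hierarchical_split(genes)
    overlaps <- do.call(rbind, lapply(list(ca, cdk, appage), function(m) {
      # a root split can peel off < 3 outlier samples; report NA then
      ov <- tryCatch(distribution_overlap(split, m), error = function(e) NULL)
      if (is.null(ov))
        return(data.frame(marker = marker_name(m),
                          overlap_percent = NA_real_,
                          mann_whitney_p = NA_real_))
      data.frame(marker = ov$marker_name,
                 overlap_percent = ov$overlap_percent,
                 mann_whitney_p = ov$mann_whitney_p)
    }))
    log_stage(stage, sprintf("groups %d/%d", sum(split$group == 1),
                             sum(split$group == 2)))
    emit(split, "dendrogram_split.tsv")
    emit(overlaps, "marker_overlaps.tsv")

    if (isTRUE(cfg$stages$fibrosis) && !is.null(fibrosis_values)) {
      stage <- "fibrosis"
      fc <- correlate_with_markers(fibrosis_values, list(ca, cdk, appage))
      log_stage(stage, sprintf("max |rho| = %.2f", max(abs(fc$rho))))
      emit(fc, "fibrosis_marker_correlations.tsv")
    }

    stage <- "de"
    bins_cdk <- bin_samples(cdk, "fifths")
    bins_app <- bin_samples(appage, "fifths")
    de_cdk <- de_genes(genes, bins_cdk, "P20", "P100", q_thr)
    de_app <- de_genes(genes, bins_app, "P20", "P100", q_thr)
    log_stage(stage, sprintf("DEGs: CDKN2A %d, AppAge %d",
                             sum(de_cdk$significant), sum(de_app$significant)))
    emit(de_cdk, "de_cdkn2a.tsv")
    emit(de_app, "de_appage.tsv")
    deg_ov <- data.frame(comparison = "CDKN2A_vs_AppAge",
                         overlap_percent = deg_overlap(de_cdk, de_app))
    bins_ca <- tryCatch(bin_samples(ca, "decades"), error = function(e) NULL)
    if (!is.null(bins_ca) && sum(bins_ca$bin == "20-30") >= 3 &&
        sum(bins_ca$bin == "61-70") >= 3) {
      de_ca <- de_genes(genes, bins_ca, "20-30", "61-70", q_thr)
      emit(de_ca, "de_ca.tsv")
      deg_ov <- rbind(deg_ov,
                      data.frame(comparison = c("CA_vs_CDKN2A", "CA_vs_AppAge"),
                                 overlap_percent = c(deg_overlap(de_ca, de_cdk),
                                                     deg_overlap(de_ca, de_app))))
    }
    emit(deg_ov, "deg_overlaps.tsv")

    if (isTRUE(cfg$stages$gsea) && !is.null(gene_sets)) {
      stage <- "gsea"
      gs <- preranked_gsea(gsea_ranking(de_cdk), gene_sets,
                           n_perm = cfg$gsea$n_perm,
                           weight_p = cfg$gsea$weight_p,
                           min_size = cfg$gsea$min_size,
                           seed = cfg$seed + 5L)
      log_stage(stage, sprintf("%d sets scored", nrow(gs)))
      emit(gs, "gsea_cdkn2a.tsv")
    }

    mirror <- NULL
    if (isTRUE(cfg$stages$mirna) && !is.null(mirnas) &&
        !is.null(predictions)) {
      stage <- "mirna"
      bam <- identify_bioage_mirnas(mirnas, cdk, bins_cdk, q_thr)
      mirror <- select_mirror_targets(predictions, genes, mirnas, bam,
                                      cdk, bins_cdk, q_thr)
      log_stage(stage, sprintf("%d BIO-AGEmiRNAs, %d mirror edges",
                               nrow(bam), nrow(mirror)))
      emit(bam, "bioage_mirnas.tsv")
      emit(mirror, "mirror_targets.tsv")
      if (!is.null(gene_sets) && nrow(mirror)) {
        net <- suppressWarnings(build_network(mirror, gene_sets, bam))
        emit(net$edges, "network_edges.tsv")
        emit(net$gene_annotation, "network_gene_annotation.tsv")
      }
    }

    if (isTRUE(cfg$stages$spm) && !is.null(panel)) {
      stage <- "spm"
      feat <- panel$feature[[1]]
      spm <- compute_spm(panel, feat)
      log_stage(stage, sprintf("SPM(%s, %s) = %.3f", feat, spm$focal_tissue,
                               spm$spm[spm$focal_tissue]))
      emit(data.frame(feature = feat, tissue = names(spm$spm),
                      spm = unname(spm$spm)), "spm.tsv")
      emit(spm$tests, "spm_pairwise_tests.tsv")
    }

    stage <- "manifest"
    cfg_file <- tempfile()
    yaml::write_yaml(unclass(cfg), cfg_file)
    config_hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)),
                           row.names = NULL, stringsAsFactors = FALSE)
    write_tsv(cbind(manifest,
                    config_hash = config_hash, seed = cfg$seed),
              file.path(cfg$outdir, "manifest.tsv"))
    list(outputs = manifest, config_hash = config_hash,
         seed = cfg$seed, stages = plan)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
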