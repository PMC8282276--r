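#' Synthetic LV cohort configuration
#'
#' Parameters of the synthetic left-ventricle cohort generator. Defaults
#' emulate the study conditions the analysis assumes: 132 donors aged 20-70
#' with inter-individual aging-rate variability, a CDKN2A-like senescence
#' gene, 14 up- and 6 down-regulated planted miRNAs whose true targets
#' mirror them, and a pool of null features.
#'
#' The latent biological age of donor i is
#' `b_i = a_min + r_i * (CA_i - a_min) + e_i` with a log-normal multiplicative
#' aging rate `r_i` (mean 1, log-sd `aging_rate_sd`) anchored at the lower
#' end of the age range, plus Gaussian noise `e_i` (sd `bio_age_noise_sd`
#' years). Age-responsive features change linearly in log2 expression with
#' `b_i` at `slope_scale` log2 units per year (jittered per feature); counts
#' are negative-binomial with common dispersion `nb_dispersion`.
#'
#' @param n_samples Cohort size (default 132).
#' @param age_range Chronological age interval in years (default `c(20, 70)`).
#' @param n_age_genes Planted age-responsive genes, split evenly up/down.
#' @param n_null_genes Genes with no age dependence (also the decoy pool).
#' @param n_mirna_up,n_mirna_down Planted miRNAs rising / falling with
#'   biological age (defaults 14 and 6).
#' @param n_null_mirna miRNAs with no age dependence (default 580, so the 20
#'   planted regulators are ~3.3% of a 600-miRNA miRNome; a wide null
#'   background also keeps per-sample miRNA library sizes stable, as in real
#'   miRNomes, so CPM normalization does not imprint the planted trends onto
#'   null features).
#' @param targets_per_mirna True mirror targets planted per planted miRNA.
#' @param decoys_per_mirna Null genes added per miRNA to the prediction map.
#' @param aging_rate_sd Log-sd of the multiplicative aging rate (0 = everyone
#'   ages at the calendar rate).
#' @param slope_scale Typical age slope, log2 units per year of biological age.
#' @param nb_dispersion Negative-binomial dispersion (1/size), > 0.
#' @param bio_age_noise_sd Sd of the additive bio-age noise, years.
#' @param mirna_coupling Extra negative partial dependence of a true target on
#'   its miRNA's realized (standardized) log2 level.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 132,
                          age_range = c(20, 70),
                          n_age_genes = 300,
                          n_null_genes = 600,
                          n_mirna_up = 14,
                          n_mirna_down = 6,
                          n_null_mirna = 580,
                          targets_per_mirna = 8,
                          decoys_per_mirna = 8,
                          aging_rate_sd = 0.25,
                          slope_scale = 0.035,
                          nb_dispersion = 0.08,
                          bio_age_noise_sd = 2,
                          mirna_coupling = 0.25,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
              n_age_genes = as.integer(n_age_genes),
              n_null_genes = as.integer(n_null_genes),
              n_mirna_up = as.integer(n_mirna_up),
              n_mirna_down = as.integer(n_mirna_down),
              n_null_mirna = as.integer(n_null_mirna),
              targets_per_mirna = as.integer(targets_per_mirna),
              decoys_per_mirna = as.integer(decoys_per_mirna),
              aging_rate_sd = aging_rate_sd, slope_scale = slope_scale,
              nb_dispersion = nb_dispersion,
              bio_age_noise_sd = bio_age_noise_sd,
              mirna_coupling = mirna_coupling, seed = as.integer(seed))
  counts <- cfg[c("n_samples", "n_age_genes", "n_null_genes", "n_mirna_up",
                  "n_mirna_down", "n_null_mirna", "targets_per_mirna",
                  "decoys_per_mirna")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must be an increasing interval")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$aging_rate_sd < 0 || cfg$bio_age_noise_sd < 0)
    stop("noise scales must be >= 0")
  if (cfg$targets_per_mirna > 0 && cfg$n_mirna_up + cfg$n_mirna_down < 1)
    stop("targets_per_mirna > 0 requires at least one planted miRNA")
  if (cfg$decoys_per_mirna > cfg$n_null_genes)
    stop("decoys_per_mirna exceeds the null-gene pool")
  structure(cfg, class = "CohortConfig")
}

nb_log2_counts <- function(n, log2_mu, dispersion) {
  stats::rnbinom(n, mu = 2^log2_mu, size = 1 / dispersion)
}

#' Generate a synthetic LV cohort with ground truth
#'
#' Draws chronological ages, latent biological ages, gene and miRNA count
#' matrices, and the planted regulatory structure described in
#' [cohort_config()]. Every planted age gene and miRNA has a linear log2
#' trend in latent biological age (sign per role); each planted miRNA's true
#' targets trend in the opposite direction and additionally depend
#' negatively on the miRNA's realized log2 level. Null features are flat.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `genes` and `mirnas` (count
#'   [expression_matrix()] objects), `samples` (a [sample_table()]), and
#'   `truth` (class `SyntheticTruth`: `latent_bio_age`, `gene_roles`,
#'   `mirna_roles`, `true_edges`, `fibrosis_truth`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  a_min <- config$age_range[1]
  sid <- sprintf("S%03d", seq_len(n))

  ca <- stats::runif(n, a_min, config$age_range[2])
  rate <- if (config$aging_rate_sd > 0)
    stats::rlnorm(n, -config$aging_rate_sd^2 / 2, config$aging_rate_sd)
  else rep(1, n)
  eps <- if (config$bio_age_noise_sd > 0)
    stats::rnorm(n, 0, config$bio_age_noise_sd) else rep(0, n)
  bio <- a_min + rate * (ca - a_min) + eps
  names(bio) <- sid
  bc <- bio - mean(bio)

  ## --- miRNAs first (targets need their realized levels) ---
  n_plant <- config$n_mirna_up + config$n_mirna_down
  n_mir <- n_plant + config$n_null_mirna
  mirna_roles <- c(rep("up", config$n_mirna_up), rep("down", config$n_mirna_down),
                   rep("null", config$n_null_mirna))
  mir_ids <- sprintf("miR-%03d", seq_len(n_mir))
  names(mirna_roles) <- mir_ids
  mir_sign <- c(up = 1, down = -1, null = 0)[mirna_roles]
  mir_mu <- stats::runif(n_mir, 3, 9)
  mir_beta <- mir_sign * stats::runif(n_mir, 0.8, 1.5) * config$slope_scale
  mirnas <- t(vapply(seq_len(n_mir), function(j) {
    nb_log2_counts(n, mir_mu[j] + mir_beta[j] * bc, config$nb_dispersion)
  }, numeric(n)))
  dimnames(mirnas) <- list(mir_ids, sid)
  # realized standardized log2 miRNA levels drive their targets
  mir_z <- t(apply(log2(mirnas + 1), 1, function(v) {
    s <- stats::sd(v); if (s == 0) rep(0, n) else (v - mean(v)) / s
  }))

  ## --- genes: cdkn2a-like, age genes, mirror targets, nulls ---
  n_up <- ceiling(config$n_age_genes / 2)
  n_dn <- config$n_age_genes - n_up
  n_tar <- n_plant * config$targets_per_mirna
  gene_roles <- c(cdkn2a_like = "cdkn2a_like",
                  stats::setNames(rep("age_up", n_up), sprintf("AGEUP%04d", seq_len(n_up))),
                  stats::setNames(rep("age_down", n_dn), sprintf("AGEDN%04d", seq_len(n_dn))),
                  stats::setNames(rep("mirror_target", n_tar),
                                  if (n_tar) sprintf("TARG%04d", seq_len(n_tar)) else character(0)),
                  stats::setNames(rep("null", config$n_null_genes),
                                  sprintf("NULL%04d", seq_len(config$n_null_genes))))
  names(gene_roles)[1] <- "CDKN2A"
  gene_ids <- names(gene_roles)
  n_gene <- length(gene_ids)

  gene_mu <- stats::runif(n_gene, 3, 9)
  gene_mu[1] <- 6  # keep the senescence marker comfortably expressed
  role_sign <- c(cdkn2a_like = 1, age_up = 1, age_down = -1,
                 mirror_target = 0, null = 0)[gene_roles]
  gene_beta <- role_sign * stats::runif(n_gene, 0.8, 1.5) * config$slope_scale
  gene_beta[1] <- 1.3 * config$slope_scale

  # assign targets to planted miRNAs in blocks, opposite-signed slopes
  true_edges <- data.frame(mirna_id = character(0), gene_id = character(0),
                           stringsAsFactors = FALSE)
  target_mirna <- integer(0)
  if (n_tar) {
    target_idx <- which(gene_roles == "mirror_target")
    target_mirna <- rep(seq_len(n_plant), each = config$targets_per_mirna)
    gene_beta[target_idx] <- -mir_sign[target_mirna] *
      stats::runif(n_tar, 0.8, 1.5) * config$slope_scale
    true_edges <- data.frame(mirna_id = mir_ids[target_mirna],
                             gene_id = gene_ids[target_idx],
                             stringsAsFactors = FALSE)
  }

  genes <- matrix(0, n_gene, n, dimnames = list(gene_ids, sid))
  tpos <- 0L
  for (g in seq_len(n_gene)) {
    lmu <- gene_mu[g] + gene_beta[g] * bc
    if (gene_roles[g] == "mirror_target") {
      tpos <- tpos + 1L
      lmu <- lmu - config$mirna_coupling * mir_z[target_mirna[tpos], ]
    }
    genes[g, ] <- nb_log2_counts(n, lmu, config$nb_dispersion)
  }

  samples <- sample_table(data.frame(sample_id = sid,
                                     chronological_age = ca,
                                     cause_of_death_class = "NCD",
                                     stringsAsFactors = FALSE))
  truth <- structure(list(latent_bio_age = bio,
                          gene_roles = gene_roles,
                          mirna_roles = mirna_roles,
                          true_edges = true_edges,
                          fibrosis_truth = NULL,
                          config = config),
                     class = "SyntheticTruth")
  list(genes = expression_matrix(genes, "counts"),
       mirnas = expression_matrix(mirnas, "counts"),
       samples = samples,
       truth = truth)
}

#' Generate a predicted-target map for the planted miRNAs
#'
#' Emulates a target-prediction database export: for each planted miRNA the
#' map contains its true regulatory edges plus `decoys_per_mirna` null genes
#' that are predicted but not actually regulated.
#'
#' @param truth `SyntheticTruth` from [generate_cohort()].
#' @param config The same [cohort_config()].
#' @return A `TargetPredictionMap` data frame (`mirna_id`, `gene_id`).
#' @export
generate_target_predictions <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 1000L)
  planted <- names(truth$mirna_roles)[truth$mirna_roles != "null"]
  nulls <- names(truth$gene_roles)[truth$gene_roles == "null"]
  decoys <- do.call(rbind, lapply(planted, function(m) {
    if (config$decoys_per_mirna == 0) return(NULL)
    data.frame(mirna_id = m,
               gene_id = sample(nulls, config$decoys_per_mirna),
               stringsAsFactors = FALSE)
  }))
  target_prediction_map(rbind(truth$true_edges, decoys))
}

#' Generate a fibrosis phenotype tied to latent biological age
#'
#' Percent interstitial fibrosis per donor as a linear function of latent
#' biological age plus Gaussian noise, clipped to `[0, 100]`.
#'
#' @param truth `SyntheticTruth` from [generate_cohort()].
#' @param slope Percent fibrosis per year of biological age.
#' @param noise_sd Gaussian noise sd, percent.
#' @param intercept Percent at biological age zero.
#' @param seed Integer seed.
#' @return Named numeric vector of per-sample percents in `[0, 100]`.
#' @export
generate_fibrosis_phenotype <- function(truth, slope = 0.5, noise_sd = 5,
                                        intercept = -5, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"), is.finite(slope))
  set.seed(seed)
  b <- truth$latent_bio_age
  fib <- intercept + slope * b +
    if (noise_sd > 0) stats::rnorm(length(b), 0, noise_sd) else 0
  fib <- pmin(pmax(fib, 0), 100)
  names(fib) <- names(b)
  fib
}
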