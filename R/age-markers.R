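#' Age-marker vector
#'
#' A per-sample vector of one of the three age markers used throughout the
#' package: chronological age (`CA`, years), `CDKN2A` expression (log2 units,
#' a single-gene senescence marker), or `AppAge` (apparent transcriptional
#' age, years).
#'
#' @param values Named numeric vector (names = sample ids), all finite.
#' @param marker_name One of `"CA"`, `"CDKN2A"`, `"AppAge"`, or another label.
#' @return Class `AgeMarkerVector`: the named numeric with a `marker_name`
#'   attribute.
#' @export
age_marker <- function(values, marker_name) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("marker values need unique sample names")
  if (any(!is.finite(values))) stop("marker values must be finite")
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values),
            marker_name = marker_name, class = "AgeMarkerVector")
}

marker_name <- function(m) attr(m, "marker_name")

#' @export
print.AgeMarkerVector <- function(x, ...) {
  cat(sprintf("AgeMarkerVector '%s' (%d samples)\n", marker_name(x), length(x)))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Single-gene senescence marker
#'
#' Projects one gene's normalized expression row out of the matrix as an age
#' marker (canonically the CDKN2A/p16 senescence locus).
#'
#' @param x A normalized [expression_matrix()].
#' @param gene_id Feature id to extract.
#' @param name Marker label; default `"CDKN2A"`.
#' @return An [age_marker()].
#' @export
cdkn2a_marker <- function(x, gene_id = "CDKN2A", name = "CDKN2A") {
  stopifnot(is_expression_matrix(x))
  if (!gene_id %in% feature_ids(x))
    stop("gene not found in matrix: ", gene_id)
  age_marker(x$values[gene_id, ], name)
}

#' Chronological-age marker from a sample table
#'
#' @param samples A [sample_table()].
#' @return An [age_marker()] named `"CA"`.
#' @export
ca_marker <- function(samples) {
  age_marker(stats::setNames(samples$chronological_age, samples$sample_id), "CA")
}

#' Calibrate an apparent-age (AppAge) model
#'
#' Screens the transcriptome for age-related genes by per-gene least-squares
#' regression of log2 expression on chronological age, keeping genes whose
#' slope is significant at a Benjamini-Hochberg FDR `q_threshold`. The
#' retained calibrations (intercept, slope, residual sd per gene) form the
#' model later inverted by [compute_appage()].
#'
#' @param x A normalized [expression_matrix()].
#' @param ca An [age_marker()] of chronological ages over the same samples.
#' @param q_threshold BH-FDR threshold for the slope test (default 0.05).
#' @param min_genes Minimum retained genes (default 10) below which fitting
#'   aborts with advice to relax the threshold.
#' @param sigma_floor Lower bound on the per-gene residual sd, so that
#'   noiseless calibration fixtures keep finite precision weights.
#' @return Class `AppAgeModel`: list with `genes` (data frame `gene_id`,
#'   `beta0`, `beta1`, `sigma`, `p`, `q`), `q_threshold`, `ca_mean`, `ca_sd`.
#' @export
fit_appage <- function(x, ca, q_threshold = 0.05, min_genes = 10,
                       sigma_floor = 1e-6) {
  stopifnot(is_expression_matrix(x), inherits(ca, "AgeMarkerVector"))
  if (x$units != "log2") stop("fit_appage expects a normalized (log2) matrix")
  if (!setequal(sample_ids(x), names(ca)))
    stop("marker samples do not match the matrix")
  a <- as.numeric(ca[sample_ids(x)])
  n <- length(a)
  if (n < 4) stop("need at least 4 samples")
  ac <- a - mean(a)
  ss_a <- sum(ac^2)
  if (ss_a == 0) stop("chronological age is constant")
  vals <- x$values
  xm <- rowMeans(vals)
  beta1 <- as.numeric(vals %*% ac) / ss_a
  beta0 <- xm - beta1 * mean(a)
  fitted <- outer(beta1, a) + beta0
  rss <- rowSums((vals - fitted)^2)
  df <- n - 2
  sigma <- sqrt(rss / df)
  se <- sqrt(pmax(rss, 0) / df / ss_a)
  tstat <- ifelse(se > 0, beta1 / se, ifelse(beta1 != 0, Inf, 0))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  keep <- q <= q_threshold & beta1 != 0
  if (sum(keep) < min_genes)
    stop(sprintf(
      "only %d gene(s) pass q <= %g (minimum %d); consider relaxing q_threshold",
      sum(keep), q_threshold, min_genes))
  genes <- data.frame(gene_id = feature_ids(x)[keep],
                      beta0 = beta0[keep], beta1 = beta1[keep],
                      sigma = pmax(sigma[keep], sigma_floor),
                      p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, q_threshold = q_threshold,
                 ca_mean = mean(a), ca_sd = stats::sd(a)),
            class = "AppAgeModel")
}

#' Compute apparent age (AppAge) per sample
#'
#' Inverts the per-gene age calibrations by precision-weighted least
#' squares: with weights `w_g = 1/sigma_g^2`, the apparent age of sample i is
#' the minimizer over `a` of `sum_g w_g (x_ig - beta0_g - beta1_g * a)^2`,
#' which has the closed form
#' `a_i = sum_g w_g beta1_g (x_ig - beta0_g) / sum_g w_g beta1_g^2`.
#' A sample whose expression sits exactly on every calibration line at age
#' `a` is therefore mapped back to `a` exactly.
#'
#' @param model An [fit_appage()] model.
#' @param x A normalized [expression_matrix()] containing all model genes.
#' @param rescale If `TRUE`, affinely rescale the result to the calibration
#'   cohort's CA mean and sd (off by default).
#' @return An [age_marker()] named `"AppAge"` (years).
#' @export
compute_appage <- function(model, x, rescale = FALSE) {
  stopifnot(inherits(model, "AppAgeModel"), is_expression_matrix(x))
  g <- model$genes
  missing <- setdiff(g$gene_id, feature_ids(x))
  if (length(missing))
    stop("model gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  vals <- x$values[g$gene_id, , drop = FALSE]
  w <- 1 / g$sigma^2
  num <- as.numeric(crossprod(vals - g$beta0, w * g$beta1))
  den <- sum(w * g$beta1^2)
  a <- num / den
  names(a) <- sample_ids(x)
  if (rescale && stats::sd(a) > 0)
    a <- model$ca_mean + (a - mean(a)) / stats::sd(a) * model$ca_sd
  age_marker(a, "AppAge")
}

#' Bin samples by an age marker
#'
#' Two schemes: `"decades"` cuts chronological-age-like markers into the
#' fixed intervals 20-30, 31-40, 41-50, 51-60, 61-70 years (closed on the
#' right: an age of exactly 30 falls in "20-30"); `"fifths"` forms rank-based
#' quintiles P20..P100 with sizes as equal as possible, ties broken
#' deterministically by sample-id order, and any remainder allotted to the
#' lowest bins.
#'
#' @param marker An [age_marker()].
#' @param scheme `"decades"` or `"fifths"`.
#' @return Class `BinAssignment`: data frame (`sample_id`, `bin`) with
#'   attributes `scheme` and `marker_name`.
#' @export
bin_samples <- function(marker, scheme = c("fifths", "decades")) {
  stopifnot(inherits(marker, "AgeMarkerVector"))
  scheme <- match.arg(scheme)
  sid <- names(marker)
  v <- as.numeric(marker)
  if (scheme == "decades") {
    if (!marker_name(marker) %in% c("CA", "AppAge"))
      stop("decade binning needs a marker in years, not '",
           marker_name(marker), "'")
    out_of_range <- sid[v < 20 | v > 70]
    if (length(out_of_range))
      stop("sample(s) outside the 20-70 y decade range: ",
           paste(out_of_range, collapse = ", "))
    bin <- as.character(cut(v, breaks = c(20, 30, 40, 50, 60, 70),
                            labels = c("20-30", "31-40", "41-50", "51-60", "61-70"),
                            include.lowest = TRUE, right = TRUE))
  } else {
    n <- length(v)
    sizes <- rep(n %/% 5L, 5)
    rem <- n %% 5L
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    labs <- c("P20", "P40", "P60", "P80", "P100")
    ord <- order(v, sid)
    bin <- character(n)
    bin[ord] <- rep(labs, times = sizes)
  }
  structure(data.frame(sample_id = sid, bin = bin, stringsAsFactors = FALSE),
            scheme = scheme, marker_name = marker_name(marker),
            class = c("BinAssignment", "data.frame"))
}

#' Pairwise Spearman correlations between age markers
#'
#' @param markers List of [age_marker()] vectors sharing samples (at least 2).
#' @return Data frame (`marker_a`, `marker_b`, `rho`, `p`); a constant
#'   marker yields `NA` rho/p for its pairs.
#' @export
marker_correlations <- function(markers) {
  if (length(markers) < 2) stop("need at least two markers")
  common <- Reduce(intersect, lapply(markers, names))
  if (length(common) < 3) stop("fewer than 3 common samples")
  nms <- vapply(markers, marker_name, character(1))
  out <- list()
  for (i in seq_along(markers)) for (j in seq_along(markers)) {
    if (j <= i) next
    a <- as.numeric(markers[[i]][common])
    b <- as.numeric(markers[[j]][common])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    out[[length(out) + 1]] <- data.frame(marker_a = nms[i], marker_b = nms[j],
                                         rho = rho, p = p,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
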