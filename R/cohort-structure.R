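#' Two-group hierarchical split of the cohort
#'
#' Agglomeratively clusters samples on the whole (normalized) transcriptome
#' and cuts the dendrogram at the root, yielding the two earliest-separated
#' branches. Defaults are correlation distance (1 - Pearson across features)
#' with average linkage — standard, scale-robust choices for transcriptome
#' sample clustering; both are configurable.
#'
#' @param x A normalized [expression_matrix()] with >= 4 samples.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage Any `stats::hclust` method (default `"average"`).
#' @return Class `DendrogramSplit`: data frame (`sample_id`, `group` in
#'   1:2) with attributes `distance`, `linkage`, `heights`, and the `hclust`
#'   object in attribute `tree`.
#' @export
hierarchical_split <- function(x, distance = c("correlation", "euclidean"),
                               linkage = "average") {
  stopifnot(is_expression_matrix(x))
  distance <- match.arg(distance)
  if (ncol(x$values) < 4) stop("need at least 4 samples to split")
  d <- if (distance == "correlation")
    stats::as.dist(1 - stats::cor(x$values))
  else stats::dist(t(x$values))
  hc <- stats::hclust(d, method = linkage)
  grp <- stats::cutree(hc, k = 2)
  structure(data.frame(sample_id = names(grp), group = unname(grp),
                       stringsAsFactors = FALSE),
            distance = distance, linkage = linkage, heights = hc$height,
            tree = hc, class = c("DendrogramSplit", "data.frame"))
}

#' Kernel-density overlap of a marker between the two cohort groups
#'
#' Fits a Gaussian kernel density per group (Silverman's rule-of-thumb
#' bandwidth) on a shared 512-point grid spanning the pooled marker range
#' extended by three bandwidths, and reports the overlapping area
#' `100 * integral of min(f1, f2)` as a percent, together with a two-sided
#' Mann-Whitney test between the group marker values. A low overlap means
#' the transcriptome-driven split separates the marker's distributions well.
#'
#' @param split A [hierarchical_split()] result (or any data frame with
#'   `sample_id` and `group` in 1:2, both groups >= 3 samples).
#' @param marker An [age_marker()] covering the split's samples.
#' @param n_grid Grid resolution (default 512).
#' @return Class `OverlapResult`: list with `marker_name`, `overlap_percent`,
#'   `mann_whitney_p`, `grid`, `density1`, `density2`, `group_sizes`.
#' @export
distribution_overlap <- function(split, marker, n_grid = 512) {
  stopifnot(inherits(marker, "AgeMarkerVector"))
  g1 <- split$sample_id[split$group == 1]
  g2 <- split$sample_id[split$group == 2]
  missing <- setdiff(c(g1, g2), names(marker))
  if (length(missing)) stop("marker missing samples: ",
                            paste(missing, collapse = ", "))
  x1 <- as.numeric(marker[g1]); x2 <- as.numeric(marker[g2])
  if (length(x1) < 3 || length(x2) < 3)
    stop("both groups need >= 3 samples")
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0)
    stop("constant marker within a group: density is degenerate")
  bw1 <- stats::bw.nrd0(x1)
  bw2 <- stats::bw.nrd0(x2)
  pad <- 3 * max(bw1, bw2)
  lo <- min(x1, x2) - pad
  hi <- max(x1, x2) + pad
  f1 <- stats::density(x1, bw = bw1, from = lo, to = hi, n = n_grid)$y
  f2 <- stats::density(x2, bw = bw2, from = lo, to = hi, n = n_grid)$y
  dx <- (hi - lo) / (n_grid - 1)
  overlap <- 100 * sum(pmin(f1, f2)) * dx
  p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
  structure(list(marker_name = marker_name(marker),
                 overlap_percent = overlap, mann_whitney_p = p,
                 grid = seq(lo, hi, length.out = n_grid),
                 density1 = f1, density2 = f2,
                 group_sizes = c(length(x1), length(x2))),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult '%s': overlap %.1f%%, Mann-Whitney p = %.3g (n = %d/%d)\n",
              x$marker_name, x$overlap_percent, x$mann_whitney_p,
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}
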