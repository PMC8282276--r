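#' Young-vs-old differential expression
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between two
#' bins of an age-marker binning, Benjamini-Hochberg adjusted across all
#' tested features. The effect size is the difference of group medians
#' (old minus young, log2 units) and sets the direction; features with a
#' zero effect are never called differential.
#'
#' Exact p-values are used whenever `wilcox.test` can compute them (small
#' groups, no ties), matching full enumeration of rank splits.
#'
#' @param x A normalized [expression_matrix()].
#' @param bins A [bin_samples()] assignment.
#' @param young_bin,old_bin Bin labels to compare (each >= 3 samples, no
#'   overlap).
#' @param q_threshold FDR threshold defining the DEG set (default 0.05).
#' @return Class `DEResult`: data frame (`feature_id`, `statistic`, `p`,
#'   `q`, `effect`, `direction`, `significant`) with comparison attributes.
#' @export
de_genes <- function(x, bins, young_bin, old_bin, q_threshold = 0.05) {
  stopifnot(is_expression_matrix(x), inherits(bins, "BinAssignment"))
  young <- bins$sample_id[bins$bin == young_bin]
  old <- bins$sample_id[bins$bin == old_bin]
  if (length(intersect(young, old))) stop("young and old bins overlap")
  if (length(young) < 3 || length(old) < 3)
    stop("both bins need >= 3 samples")
  missing <- setdiff(c(young, old), sample_ids(x))
  if (length(missing)) stop("bin samples absent from matrix: ",
                            paste(missing, collapse = ", "))
  vy <- x$values[, young, drop = FALSE]
  vo <- x$values[, old, drop = FALSE]
  res <- t(vapply(seq_len(nrow(vy)), function(i) {
    wt <- suppressWarnings(stats::wilcox.test(vo[i, ], vy[i, ]))
    c(wt$statistic, wt$p.value)
  }, numeric(2)))
  effect <- apply(vo, 1, stats::median) - apply(vy, 1, stats::median)
  q <- stats::p.adjust(res[, 2], "BH")
  direction <- ifelse(effect > 0, "up", ifelse(effect < 0, "down", "none"))
  structure(data.frame(feature_id = feature_ids(x),
                       statistic = res[, 1], p = res[, 2], q = q,
                       effect = effect, direction = direction,
                       significant = q <= q_threshold & effect != 0,
                       stringsAsFactors = FALSE, row.names = NULL),
            young_bin = young_bin, old_bin = old_bin,
            q_threshold = q_threshold,
            class = c("DEResult", "data.frame"))
}

#' Direction-aware overlap between two DEG sets
#'
#' Percent of significant features in `a` whose feature id *and* direction
#' both reappear among the significant features of `b`; a direction
#' mismatch counts as a miss.
#'
#' @param a,b `DEResult` objects (or data frames with `feature_id`,
#'   `direction`, `significant`).
#' @return A percent in `[0, 100]` (`NaN` if `a` has no significant
#'   features).
#' @export
deg_overlap <- function(a, b) {
  ka <- a[a$significant, c("feature_id", "direction")]
  kb <- b[b$significant, c("feature_id", "direction")]
  if (!nrow(ka)) return(NaN)
  100 * mean(paste(ka$feature_id, ka$direction) %in%
               paste(kb$feature_id, kb$direction))
}
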