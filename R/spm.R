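#' SPM tissue-specificity score with pairwise tests
#'
#' The Specificity Measure of a feature in tissue t is the squared cosine
#' between the panel's mean-expression profile and tissue t's indicator
#' vector: with `m_t` the feature's mean expression in tissue t,
#' `SPM_t = m_t^2 / sum_j m_j^2`. Scores lie in `[0, 1]`, sum to 1 across
#' tissues whenever any mean is nonzero, and are invariant to global
#' positive rescaling of the panel. The focal tissue (highest mean by
#' default) is additionally compared with every other tissue by two-sided
#' Mann-Whitney tests, BH-adjusted across the pairs.
#'
#' @param panel A [generate_tissue_panel()]-style long data frame
#'   (`feature`, `tissue`, `sample`, `value`) with >= 2 tissues.
#' @param feature_id Feature to score.
#' @param focal_tissue Tissue for the pairwise tests; default the tissue
#'   with the largest mean expression.
#' @return Class `SPMResult`: list with `feature_id`, `spm` (named vector,
#'   all `NA` for an all-zero profile), `focal_tissue`, and `tests`
#'   (data frame `tissue`, `p`, `q`).
#' @export
compute_spm <- function(panel, feature_id, focal_tissue = NULL) {
  sub <- panel[panel$feature == feature_id, , drop = FALSE]
  if (!nrow(sub)) stop("feature not in panel: ", feature_id)
  tissues <- unique(sub$tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues")
  m <- vapply(tissues, function(tt) mean(sub$value[sub$tissue == tt]),
              numeric(1))
  names(m) <- tissues
  denom <- sum(m^2)
  spm <- if (denom == 0) stats::setNames(rep(NA_real_, length(m)), tissues)
  else m^2 / denom
  if (is.null(focal_tissue))
    focal_tissue <- tissues[which.max(m)]
  if (!focal_tissue %in% tissues) stop("unknown focal tissue: ", focal_tissue)
  others <- setdiff(tissues, focal_tissue)
  fv <- sub$value[sub$tissue == focal_tissue]
  p <- vapply(others, function(tt) {
    suppressWarnings(stats::wilcox.test(fv, sub$value[sub$tissue == tt])$p.value)
  }, numeric(1))
  tests <- data.frame(tissue = others, p = p,
                      q = stats::p.adjust(p, "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(feature_id = feature_id, spm = spm,
                 focal_tissue = focal_tissue, tests = tests),
            class = "SPMResult")
}

#' @export
print.SPMResult <- function(x, ...) {
  cat(sprintf("SPMResult '%s': focal %s SPM = %.3f (max elsewhere %.3f)\n",
              x$feature_id, x$focal_tissue, x$spm[x$focal_tissue],
              max(x$spm[names(x$spm) != x$focal_tissue])))
  invisible(x)
}
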