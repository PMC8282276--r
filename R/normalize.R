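#' Library-size normalization
#'
#' Scales raw counts per sample to counts-per-million and applies
#' `log2(x + 1)`. All downstream statistics in the package are rank-based
#' (Spearman, Mann-Whitney), so this CPM approximation of RPKM-style
#' normalization leaves every result invariant to per-sample scaling choices;
#' gene length is deliberately not part of the data model.
#'
#' @param x An [expression_matrix()] with `units = "counts"`.
#' @param method Only `"cpm_log2"` is implemented.
#' @param pseudocount Added before the log; default 1 (zero-preserving).
#' @return An `ExpressionMatrix` with `units = "log2"`.
#' @export
normalize_expression <- function(x, method = c("cpm_log2"), pseudocount = 1) {
  stopifnot(is_expression_matrix(x))
  method <- match.arg(method)
  if (x$units != "counts")
    stop("normalize_expression expects raw counts; units are '", x$units, "'")
  tot <- colSums(x$values)
  bad <- colnames(x$values)[tot == 0]
  if (length(bad))
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  cpm <- sweep(x$values, 2, tot, "/") * 1e6
  expression_matrix(log2(cpm + pseudocount), units = "log2")
}

#' Remove weakly expressed features
#'
#' Keeps features whose value is at least `min_value` in at least
#' `min_fraction` of samples; feature order is preserved.
#'
#' @param x A normalized [expression_matrix()].
#' @param min_value Expression threshold, in the matrix's units.
#' @param min_fraction Required fraction of samples in `[0, 1]`.
#' @return Filtered `ExpressionMatrix` (may be empty, with a warning).
#' @export
filter_low_expression <- function(x, min_value = 1, min_fraction = 0.2) {
  stopifnot(is_expression_matrix(x))
  if (min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must be in [0, 1]")
  keep <- rowMeans(x$values >= min_value) >= min_fraction
  if (!any(keep)) warning("no features pass the expression filter")
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}
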