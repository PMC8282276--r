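#' Expression matrix container
#'
#' A light S3 container for a features-by-samples expression matrix, in the
#' style of limma's list-based classes. Rows are genes or miRNAs, columns are
#' samples; `units` records where the values sit in the normalization
#' lifecycle so downstream functions can guard their preconditions (e.g.
#' [normalize_expression()] refuses anything but raw counts).
#'
#' @param values Numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids). Values must be finite,
#'   and non-negative unless `units = "log2"`.
#' @param units One of `"counts"`, `"cpm"`, `"rpkm_like"`, `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `units`.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, units = c("counts", "cpm", "rpkm_like", "log2")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (features) and colnames (samples)")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (units != "log2" && any(values < 0))
    stop("expression values must be non-negative before log transform")
  structure(list(values = values, units = units), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

#' Per-sample metadata table
#'
#' Validates a sample annotation data frame: one row per sample, a
#' `sample_id` column, chronological ages inside a plausible human range, and
#' (optionally) exact agreement with the samples of a paired expression
#' matrix. Extra covariate columns pass through untouched.
#'
#' @param df Data frame with at least `sample_id` and `chronological_age`
#'   columns; `cause_of_death_class` and further covariates are optional.
#' @param matrix Optional `ExpressionMatrix` whose sample ids must match
#'   `df$sample_id` exactly (as sets).
#' @return `df`, with class `c("SampleTable", "data.frame")`.
#' @export
sample_table <- function(df, matrix = NULL) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  need <- c("sample_id", "chronological_age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  age <- df$chronological_age
  if (any(!is.finite(age)) || any(age < 0 | age > 120))
    stop("chronological_age must be finite and within [0, 120]")
  if (!is.null(matrix)) {
    if (!setequal(df$sample_id, sample_ids(matrix)))
      stop("metadata samples do not match the expression matrix")
  }
  class(df) <- unique(c("SampleTable", class(df)))
  df
}
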