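#' Read an expression matrix from GCT 1.2 or TSV
#'
#' GCT 1.2 is the two-header-line dialect: `#1.2`, then
#' `<n_features><TAB><n_samples>`, then a header row starting
#' `Name<TAB>Description` followed by sample ids. TSV is a plain matrix with
#' feature ids in the first column and sample ids in the header.
#'
#' @param path File path.
#' @param format `"gct"` or `"tsv"`; default guesses from the file extension.
#' @param units Units to stamp on the result (files do not carry units);
#'   default `"counts"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv"),
                            units = "counts") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(lines)))
    stop("empty expression file: ", path)
  if (format == "gct") {
    if (length(lines) < 3 || !grepl("^#1\\.2", lines[[1]]))
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]))
    if (length(dims) < 2 || any(is.na(dims[1:2])))
      stop("malformed GCT dimension line (line 2): '", lines[[2]], "'")
    body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (nrow(body) != dims[[1]])
      stop(sprintf(
        "GCT dimension line declares %d features but file contains %d (line 2: '%s')",
        dims[[1]], nrow(body), lines[[2]]))
    if (ncol(body) - 2L != dims[[2]])
      stop(sprintf(
        "GCT dimension line declares %d samples but file contains %d (line 2: '%s')",
        dims[[2]], ncol(body) - 2L, lines[[2]]))
    vals <- as.matrix(body[, -(1:2), drop = FALSE])
    rownames(vals) <- as.character(body[[1]])
  } else {
    body <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(body) < 2) stop("TSV matrix needs an id column plus >= 1 sample")
    vals <- as.matrix(body[, -1, drop = FALSE])
    rownames(vals) <- as.character(body[[1]])
  }
  storage.mode(vals) <- "double"
  expression_matrix(vals, units = units)
}

#' Write an expression matrix as GCT 1.2 or TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param format `"gct"` or `"tsv"`; default from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("auto", "gct", "tsv")) {
  stopifnot(is_expression_matrix(x))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  df <- as.data.frame(x$values, check.names = FALSE)
  if (format == "gct") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(df), ncol(df), sep = "\t")), con)
    out <- cbind(Name = rownames(df), Description = rownames(df), df)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- cbind(feature_id = rownames(df), df)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write gene set collections (GMT)
#'
#' GMT is tab-separated: set id, description, then member ids. Every set must
#' be non-empty and ids must not contain tabs (guaranteed by the format).
#'
#' @param path File path.
#' @return A named list of character vectors with a `description` attribute
#'   per set; class `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line with no members: '", substr(ln, 1, 60), "'")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", parts[[1]])
    attr(members, "description") <- parts[[2]]
    sets[[parts[[1]]]] <- members
  }
  if (anyDuplicated(names(sets))) stop("duplicate set ids in GMT")
  structure(sets, class = "GeneSetCollection")
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (or `GeneSetCollection`).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(id, desc, as.character(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write miRNA target prediction maps
#'
#' Two-column TSV edge lists (`mirna_id`, `gene_id`), the interchange format
#' for predicted miRNA-target relations exported from prediction databases.
#'
#' @param path File path.
#' @return Data frame with columns `mirna_id`, `gene_id`; class
#'   `TargetPredictionMap`.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stop("target map must have columns mirna_id, gene_id")
  target_prediction_map(df)
}

#' @rdname read_target_map
#' @param map A `TargetPredictionMap` (or data frame with the two columns).
#' @export
write_target_map <- function(map, path) {
  utils::write.table(map[, c("mirna_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

target_prediction_map <- function(df) {
  df <- as.data.frame(df)[, c("mirna_id", "gene_id")]
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  class(df) <- unique(c("TargetPredictionMap", class(df)))
  df
}
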