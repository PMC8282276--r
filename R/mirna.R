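#' Identify biological-age-related miRNAs (BIO-AGEmiRNAs)
#'
#' A miRNA is called biological-age related when it is (i) differentially
#' expressed between the biologically youngest (P20) and oldest (P100)
#' fifths of the cohort, binned by CDKN2A expression, at BH FDR
#' `q_threshold`, and (ii) significantly Spearman-correlated with CDKN2A
#' expression across all samples at the same FDR. Its direction is the sign
#' of that correlation.
#'
#' @param mirna_matrix Normalized miRNA [expression_matrix()].
#' @param cdkn2a The CDKN2A [age_marker()] the bins were built from.
#' @param bins A fifths [bin_samples()] of `cdkn2a` (checked).
#' @param q_threshold FDR for both filters (default 0.05).
#' @return Class `BioAgeMiRNA` data frame (`mirna_id`, `direction`,
#'   `rho_cdkn2a`, `q_de`, `q_corr`), one row per retained miRNA.
#' @export
identify_bioage_mirnas <- function(mirna_matrix, cdkn2a, bins,
                                   q_threshold = 0.05) {
  stopifnot(is_expression_matrix(mirna_matrix),
            inherits(cdkn2a, "AgeMarkerVector"),
            inherits(bins, "BinAssignment"))
  if (attr(bins, "scheme") != "fifths" ||
      !identical(attr(bins, "marker_name"), marker_name(cdkn2a)))
    stop("`bins` must be fifths of the supplied CDKN2A marker")
  de <- de_genes(mirna_matrix, bins, "P20", "P100", q_threshold)
  common <- intersect(sample_ids(mirna_matrix), names(cdkn2a))
  cd <- as.numeric(cdkn2a[common])
  vals <- mirna_matrix$values[, common, drop = FALSE]
  cc <- t(apply(vals, 1, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(v, cd, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }))
  q_corr <- stats::p.adjust(cc[, 2], "BH")
  keep <- de$significant & !is.na(q_corr) & q_corr <= q_threshold
  out <- data.frame(mirna_id = de$feature_id[keep],
                    direction = ifelse(cc[keep, 1] > 0, "up", "down"),
                    rho_cdkn2a = cc[keep, 1],
                    q_de = de$q[keep], q_corr = q_corr[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, q_threshold = q_threshold,
            class = c("BioAgeMiRNA", "data.frame"))
}

#' Select mirror-expressed targets of BIO-AGEmiRNAs
#'
#' Filters a predicted target map down to pairs whose target gene mirrors
#' its miRNA across biological aging. A predicted (miRNA, gene) pair is
#' retained when all enabled filters hold at BH FDR `q_threshold`:
#' \describe{
#'   \item{anticorrelation}{Spearman(gene, miRNA) < 0 and significant
#'     (BH across all tested pairs);}
#'   \item{differential}{the gene is differentially expressed between the
#'     P20 and P100 CDKN2A fifths with direction opposite the miRNA's;}
#'   \item{cdkn2a}{Spearman(gene, CDKN2A) is significant with sign opposite
#'     the miRNA's `rho_cdkn2a`.}
#' }
#' Gene-level tests are BH-adjusted across the tested candidate genes.
#'
#' @param predictions A [read_target_map()] / [generate_target_predictions()]
#'   map.
#' @param gene_matrix Normalized gene [expression_matrix()].
#' @param mirna_matrix Normalized miRNA [expression_matrix()].
#' @param mirnas An [identify_bioage_mirnas()] table.
#' @param cdkn2a The CDKN2A [age_marker()].
#' @param bins The fifths [bin_samples()] of `cdkn2a`.
#' @param q_threshold FDR for every filter (default 0.05).
#' @param filters Character subset of
#'   `c("anticorrelation", "differential", "cdkn2a")`; all three by default.
#' @return Class `MirrorTargetTable` data frame (`mirna_id`, `gene_id`,
#'   `gene_direction`, `rho_gene_cdkn2a`, `q_gene_cdkn2a`, `rho_gene_mirna`,
#'   `q_gene_mirna`, `q_gene_de`); possibly empty.
#' @export
select_mirror_targets <- function(predictions, gene_matrix, mirna_matrix,
                                  mirnas, cdkn2a, bins, q_threshold = 0.05,
                                  filters = c("anticorrelation",
                                              "differential", "cdkn2a")) {
  stopifnot(is_expression_matrix(gene_matrix),
            is_expression_matrix(mirna_matrix),
            inherits(mirnas, "BioAgeMiRNA"))
  filters <- match.arg(filters, several.ok = TRUE)
  pred <- predictions[predictions$mirna_id %in% mirnas$mirna_id &
                        predictions$gene_id %in% feature_ids(gene_matrix), ,
                      drop = FALSE]
  empty <- structure(data.frame(mirna_id = character(0), gene_id = character(0),
                                gene_direction = character(0),
                                rho_gene_cdkn2a = numeric(0),
                                q_gene_cdkn2a = numeric(0),
                                rho_gene_mirna = numeric(0),
                                q_gene_mirna = numeric(0),
                                q_gene_de = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("MirrorTargetTable", "data.frame"))
  if (!nrow(pred)) return(empty)

  common <- intersect(sample_ids(gene_matrix), names(cdkn2a))
  cd <- as.numeric(cdkn2a[common])
  cand <- unique(pred$gene_id)
  gv <- gene_matrix$values[cand, common, drop = FALSE]

  # gene-level: DE between fifths and correlation with CDKN2A
  sub <- gene_matrix
  sub$values <- gene_matrix$values[cand, , drop = FALSE]
  de <- de_genes(sub, bins, "P20", "P100", q_threshold)
  gcc <- t(apply(gv, 1, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(v, cd, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }))
  gq_corr <- stats::p.adjust(gcc[, 2], "BH")
  gi <- match(pred$gene_id, cand)
  mi <- match(pred$mirna_id, mirnas$mirna_id)

  # pair-level: anticorrelation with the miRNA, BH across tested pairs
  mv <- mirna_matrix$values[, common, drop = FALSE]
  pair <- t(vapply(seq_len(nrow(pred)), function(k) {
    g <- gv[gi[k], ]; m <- mv[pred$mirna_id[k], ]
    if (stats::sd(g) == 0 || stats::sd(m) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(g, m, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  pq <- stats::p.adjust(pair[, 2], "BH")

  mdir <- mirnas$direction[mi]
  gdir <- de$direction[gi]
  keep <- rep(TRUE, nrow(pred))
  if ("anticorrelation" %in% filters)
    keep <- keep & !is.na(pq) & pair[, 1] < 0 & pq <= q_threshold
  if ("differential" %in% filters)
    keep <- keep & de$significant[gi] &
      ((mdir == "up" & gdir == "down") | (mdir == "down" & gdir == "up"))
  if ("cdkn2a" %in% filters)
    keep <- keep & !is.na(gq_corr[gi]) & gq_corr[gi] <= q_threshold &
      sign(gcc[gi, 1]) == -sign(mirnas$rho_cdkn2a[mi])
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(empty)
  out <- data.frame(mirna_id = pred$mirna_id[keep],
                    gene_id = pred$gene_id[keep],
                    gene_direction = gdir[keep],
                    rho_gene_cdkn2a = gcc[gi[keep], 1],
                    q_gene_cdkn2a = gq_corr[gi[keep]],
                    rho_gene_mirna = pair[keep, 1],
                    q_gene_mirna = pq[keep],
                    q_gene_de = de$q[gi[keep]],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("MirrorTargetTable", "data.frame"))
}

#' Build the cardiac miRNA-gene regulatory network
#'
#' Restricts a mirror-target table to genes annotated in at least one
#' cardiac gene set, keeps the `top_k` up- and `top_k` down-regulated
#' miRNAs ranked by the absolute strength of their CDKN2A correlation, and
#' reports each retained miRNA's coverage of the network's gene set.
#'
#' @param table A [select_mirror_targets()] table.
#' @param cardiac_sets A [read_gmt()] collection of cardiac gene sets.
#' @param mirnas The [identify_bioage_mirnas()] table (for directions and
#'   correlation strengths).
#' @param top_k miRNAs kept per direction (default 5).
#' @return Class `RegulatoryNetwork`: list with `edges` (data frame
#'   `mirna_id`, `gene_id`), `gene_annotation` (data frame `gene_id`,
#'   `sets`), and `coverage` (named fraction of network genes targeted per
#'   miRNA). Empty (with a warning) when no table gene is cardiac.
#' @export
build_network <- function(table, cardiac_sets, mirnas, top_k = 5) {
  stopifnot(inherits(mirnas, "BioAgeMiRNA"))
  if (top_k < 1) stop("top_k must be >= 1")
  membership <- lapply(names(cardiac_sets), function(id) {
    data.frame(gene_id = as.character(cardiac_sets[[id]]), set = id,
               stringsAsFactors = FALSE)
  })
  membership <- do.call(rbind, membership)
  cardiac_genes <- unique(membership$gene_id)
  tab <- table[table$gene_id %in% cardiac_genes, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no mirror target belongs to a cardiac gene set; empty network")
    return(structure(list(edges = data.frame(mirna_id = character(0),
                                             gene_id = character(0)),
                          gene_annotation = data.frame(gene_id = character(0),
                                                       sets = character(0)),
                          coverage = numeric(0)),
                     class = "RegulatoryNetwork"))
  }
  ranked <- mirnas[mirnas$mirna_id %in% tab$mirna_id, ]
  ranked <- ranked[order(-abs(ranked$rho_cdkn2a)), ]
  keep_mir <- c(utils::head(ranked$mirna_id[ranked$direction == "up"], top_k),
                utils::head(ranked$mirna_id[ranked$direction == "down"], top_k))
  tab <- tab[tab$mirna_id %in% keep_mir, , drop = FALSE]
  net_genes <- unique(tab$gene_id)
  ann <- stats::aggregate(set ~ gene_id,
                          membership[membership$gene_id %in% net_genes, ],
                          function(s) paste(sort(unique(s)), collapse = ";"))
  names(ann) <- c("gene_id", "sets")
  coverage <- vapply(keep_mir, function(m) {
    length(unique(tab$gene_id[tab$mirna_id == m])) / length(net_genes)
  }, numeric(1))
  structure(list(edges = tab[, c("mirna_id", "gene_id")],
                 gene_annotation = ann,
                 coverage = coverage),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d edges, %d genes, %d miRNAs\n",
              nrow(x$edges), length(unique(x$edges$gene_id)),
              length(unique(x$edges$mirna_id))))
  invisible(x)
}
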