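## Weighted Kolmogorov-Smirnov running-sum enrichment score for one set.
## scores must already be sorted decreasing; hit_idx indexes into that order.
gsea_es <- function(sorted_scores, hit_idx, weight_p = 1) {
  n <- length(sorted_scores)
  nh <- length(hit_idx)
  inc <- numeric(n)
  w <- abs(sorted_scores[hit_idx])^weight_p
  if (sum(w) == 0) w <- rep(1, nh)  # all-zero scores: unweighted hits
  inc[hit_idx] <- w / sum(w)
  inc[-hit_idx] <- -1 / (n - nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA on a pre-ranked
#' feature list. Hits increment the running sum proportionally to
#' `|score|^weight_p` (normalized over the set), misses decrement it by
#' `1/(N - |S|)`; the enrichment score ES is the maximum signed deviation.
#' The null distribution is built by permuting set membership (`n_perm`
#' random sets of the same size, seeded), which keeps small runs
#' deterministic; NES = ES divided by the mean |null ES| of matching sign;
#' nominal p is the matching-sign permutation tail, and FDR is
#' Benjamini-Hochberg across sets within each ES sign.
#'
#' @param scores Named numeric ranking (feature -> score), no duplicate
#'   names; sorted internally in decreasing order.
#' @param sets A [read_gmt()] collection or named list of feature vectors.
#' @param n_perm Membership permutations (default 1000).
#' @param weight_p Hit weight exponent (default 1; 0 = unweighted KS).
#' @param min_size Minimum set size after intersection with the ranking
#'   (default 5); smaller sets are skipped with a warning.
#' @param seed Integer seed for the permutations.
#' @return Class `GSEAResult`: data frame (`set_id`, `size`, `es`, `nes`,
#'   `p`, `q`, `leading_edge` as a comma-joined string).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000, weight_p = 1,
                           min_size = 5, seed = 1L) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("`scores` must be uniquely named by feature")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  feats <- names(s)
  n <- length(s)
  set.seed(seed)
  rows <- list()
  for (id in names(sets)) {
    hit_idx <- which(feats %in% sets[[id]])
    nh <- length(hit_idx)
    if (nh < max(min_size, 1)) {
      warning("set '", id, "' has fewer than ", max(min_size, 1),
              " features in the ranking; skipped")
      next
    }
    if (nh == n) {
      warning("set '", id, "' covers the whole ranking; skipped")
      next
    }
    obs <- gsea_es(s, hit_idx, weight_p)
    null_es <- vapply(seq_len(n_perm), function(b) {
      gsea_es(s, sort(sample.int(n, nh)), weight_p)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- if (length(same))
      (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    else NA_real_
    le <- if (obs$es >= 0) feats[hit_idx[hit_idx <= obs$peak]]
    else feats[hit_idx[hit_idx >= obs$peak]]
    rows[[id]] <- data.frame(set_id = id, size = nh, es = obs$es, nes = nes,
                             p = p, leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(structure(data.frame(set_id = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p = numeric(0), q = numeric(0),
                                leading_edge = character(0)),
                     class = c("GSEAResult", "data.frame")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (sgn in c(-1, 1)) {
    idx <- which(sign(out$es) == sgn)
    if (length(idx)) out$q[idx] <- stats::p.adjust(out$p[idx], "BH")
  }
  out <- out[, c("set_id", "size", "es", "nes", "p", "q", "leading_edge")]
  structure(out, class = c("GSEAResult", "data.frame"))
}

#' Ranking metric for pre-ranked GSEA from a DE result
#'
#' Signed `-log10(p)`: positive for features up in old, negative for down.
#'
#' @param de A [de_genes()] result.
#' @param cap Cap on `-log10(p)` to keep zero-p features finite.
#' @return Named numeric scores.
#' @export
gsea_ranking <- function(de, cap = 300) {
  sgn <- ifelse(de$direction == "down", -1, 1)
  stats::setNames(sgn * pmin(-log10(pmax(de$p, 1e-300)), cap), de$feature_id)
}
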