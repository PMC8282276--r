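## H&E stain vectors (Ruifrok & Johnston), columns normalized to unit length.
he_stain_matrix <- function() {
  H <- c(0.650, 0.704, 0.286)
  E <- c(0.072, 0.990, 0.105)
  cbind(H = H / sqrt(sum(H^2)), E = E / sqrt(sum(E^2)))
}

#' Quantify percent fibrosis from an H&E image
#'
#' Estimates the extracellular-matrix (ECM) area fraction of the tissue,
#' exploiting H&E's color contrast: eosin stains the ECM light pink while
#' myocytes stain dark. Steps: (1) tissue vs near-white background by a
#' luminance threshold; (2) optical-density stain separation with standard
#' Ruifrok-Johnston hematoxylin/eosin vectors; (3) tissue pixels classified
#' ECM (eosin-dominant and high luminance) vs myocyte by an Otsu threshold
#' on the eosin/(eosin+hematoxylin) deconvolution ratio; (4) a 3x3 binary
#' majority vote to fill pinholes and drop specks (pixel-level
#' classification noise is symmetric, so this denoising is unbiased),
#' followed by morphological opening of the ECM mask; (5) percent =
#' 100 * ECM / tissue pixels.
#'
#' When the Otsu split is degenerate — the two candidate classes' mean
#' ratios differ by less than `min_separation`, as happens on essentially
#' single-class tissue (no ECM at all, or wall-to-wall ECM) — the whole
#' tissue is assigned to one class by whether its mean ratio exceeds 0.5.
#'
#' @param image RGB array (h x w x 3, values in `[0, 1]`) or a PNG path.
#' @param background_luminance Tissue = mean-RGB luminance below this
#'   (default 0.9; backgrounds are near-white).
#' @param ecm_min_luminance ECM pixels must additionally exceed this
#'   luminance (default 0.5), encoding "light pink vs dark".
#' @param opening_radius Radius (px) of the morphological opening disc
#'   (default 1; 0 disables).
#' @param min_separation Otsu degeneracy guard (see Details).
#' @param stains 3 x 2 matrix of hematoxylin/eosin optical-density vectors.
#' @return Class `FibrosisResult`: list with `fibrosis_percent`,
#'   `tissue_mask`, `ecm_mask` (logical matrices, `ecm_mask` contained in
#'   `tissue_mask`), and `parameters`.
#' @export
quantify_fibrosis <- function(image,
                              background_luminance = 0.9,
                              ecm_min_luminance = 0.5,
                              opening_radius = 1,
                              min_separation = 0.25,
                              stains = he_stain_matrix()) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("expected an RGB image (h x w x 3 array)")
  img <- image[, , 1:3, drop = FALSE]
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  tissue <- lum < background_luminance
  if (mean(tissue) <= 0.01) stop("no tissue detected (image nearly all background)")

  od <- -log10(pmax(img, 1e-3))
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- odm %*% stains %*% solve(crossprod(stains))
  cH <- pmax(conc[, 1], 0); cE <- pmax(conc[, 2], 0)
  ratio <- matrix(cE / (cE + cH + 1e-12), nrow(lum), ncol(lum))

  rt <- ratio[tissue]
  thr <- otsu_threshold(rt)
  hi <- rt > thr
  if (!any(hi) || all(hi) ||
      abs(mean(rt[hi]) - mean(rt[!hi])) < min_separation) {
    eosin_dom <- if (mean(rt) > 0.5) tissue else (tissue & FALSE)
  } else {
    eosin_dom <- tissue & ratio > thr
  }
  ecm <- eosin_dom & lum > ecm_min_luminance

  if (any(ecm)) {
    cnt <- as.matrix(EBImage::filter2(EBImage::Image(ecm * 1),
                                      matrix(1, 3, 3) / 9))
    ecm <- cnt >= 5 / 9 - 1e-9
  }
  if (opening_radius > 0 && any(ecm)) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    ecm <- EBImage::opening(EBImage::Image(ecm * 1), brush) > 0.5
    ecm <- matrix(as.logical(ecm), nrow(lum), ncol(lum))
  }
  ecm <- ecm & tissue
  structure(list(fibrosis_percent = 100 * sum(ecm) / sum(tissue),
                 tissue_mask = tissue, ecm_mask = ecm,
                 parameters = list(background_luminance = background_luminance,
                                   ecm_min_luminance = ecm_min_luminance,
                                   opening_radius = opening_radius,
                                   min_separation = min_separation)),
            class = "FibrosisResult")
}

## Otsu threshold of a numeric vector in [0,1] via 256-bin histogram.
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  brks <- seq(0, 1, length.out = n_bins + 1)
  h <- tabulate(findInterval(v, brks, all.inside = TRUE), n_bins)
  mids <- (brks[-1] + brks[-(n_bins + 1)]) / 2
  w <- cumsum(h); tw <- w[n_bins]
  mu <- cumsum(h * mids); tmu <- mu[n_bins]
  w1 <- w[-n_bins]; w2 <- tw - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1)
  between[valid] <- (tmu * w1[valid] - tw * mu[-n_bins][valid])^2 /
    (w1[valid] * w2[valid])
  mids[which.max(between)]
}

#' @export
print.FibrosisResult <- function(x, ...) {
  cat(sprintf("FibrosisResult: %.2f%% ECM of %d tissue pixels\n",
              x$fibrosis_percent, sum(x$tissue_mask)))
  invisible(x)
}

#' Correlate a per-sample quantity with age markers
#'
#' Spearman correlation of any per-sample numeric (a fibrosis percentage, a
#' single gene's expression row, a plasma measurement) with each supplied
#' age marker, Benjamini-Hochberg adjusted across the tested markers.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param markers List of [age_marker()] vectors.
#' @return Data frame (`marker`, `rho`, `p`, `q`); constant inputs give
#'   `NA` rho.
#' @export
correlate_with_markers <- function(values, markers) {
  if (is.null(names(values))) stop("`values` must be named by sample id")
  rows <- lapply(markers, function(m) {
    common <- intersect(names(values), names(m))
    if (length(common) < 5) stop("fewer than 5 common samples for marker ",
                                 marker_name(m))
    v <- values[common]; mm <- as.numeric(m[common])
    if (stats::sd(v) == 0 || stats::sd(mm) == 0)
      return(data.frame(marker = marker_name(m), rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(v, mm, method = "spearman"))
    data.frame(marker = marker_name(m), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}
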