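#' Generate a synthetic H&E left-ventricle histology image
#'
#' Builds an RGB image imitating the color contrast an H&E stain produces in
#' myocardium: a disc of tissue on a white background, dark blue-purple
#' myocyte texture, and light-pink extracellular-matrix (ECM) ribbons laid
#' down as random-walk strands until the ECM/tissue pixel ratio is within
#' 0.005 of the requested fraction. The exact ECM mask is returned as ground
#' truth for validating [quantify_fibrosis()]. Colors are flat with mild
#' texture noise; this is a color-contrast fixture, not a stain simulation.
#'
#' @param ecm_fraction Target ECM area fraction of the tissue, in `[0, 1]`.
#' @param size Image side in pixels (square); default 128.
#' @param seed Integer seed.
#' @param myocyte_rgb,ecm_rgb Base colors.
#' @param noise_sd Per-channel Gaussian texture noise sd.
#' @return List with `image` (size x size x 3 array in `[0, 1]`),
#'   `ecm_mask` and `tissue_mask` (logical matrices), and `ecm_fraction`
#'   (the achieved mask fraction).
#' @export
generate_histology_image <- function(ecm_fraction, size = 128, seed = 1L,
                                     myocyte_rgb = c(0.40, 0.25, 0.55),
                                     ecm_rgb = c(0.95, 0.72, 0.84),
                                     noise_sd = 0.025) {
  if (ecm_fraction < 0 || ecm_fraction > 1)
    stop("ecm_fraction must be in [0, 1]")
  set.seed(seed)
  cx <- (size + 1) / 2
  r2 <- (0.45 * size)^2
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  tissue <- (xg - cx)^2 + (yg - cx)^2 <= r2
  n_tissue <- sum(tissue)

  ecm <- matrix(FALSE, size, size)
  tol <- 0.005
  if (ecm_fraction >= 1 - tol) {
    ecm <- tissue
  } else if (ecm_fraction > tol) {
    # solid 3x3 stamp: ribbons get flat cross-sections that survive a
    # radius-1 morphological opening; < tol * tissue area per step for
    # size >= 64
    off <- expand.grid(dx = -1:1, dy = -1:1)
    stamp <- function(x, y) {
      xs <- pmin(pmax(x + off$dx, 1), size)
      ys <- pmin(pmax(y + off$dy, 1), size)
      idx <- cbind(xs, ys)
      idx <- idx[tissue[idx], , drop = FALSE]
      ecm[idx] <<- TRUE
    }
    frac <- 0
    steps <- 0L
    max_steps <- 80L * n_tissue  # generous; unreachable targets error out
    while (frac < ecm_fraction - tol) {
      # new strand from a random tissue pixel
      x <- stats::runif(1, cx - sqrt(r2), cx + sqrt(r2))
      y <- stats::runif(1, cx - sqrt(r2), cx + sqrt(r2))
      ang <- stats::runif(1, 0, 2 * pi)
      len <- sample(20:60, 1)
      for (s in seq_len(len)) {
        steps <- steps + 1L
        if (steps > max_steps)
          stop("ecm_fraction ", ecm_fraction,
               " unreachable within 0.005 at size ", size)
        ang <- ang + stats::rnorm(1, 0, 0.35)
        x <- x + cos(ang); y <- y + sin(ang)
        xi <- round(x); yi <- round(y)
        if (xi < 2 || xi > size - 1 || yi < 2 || yi > size - 1 || !tissue[xi, yi])
          break
        stamp(xi, yi)
        frac <- sum(ecm) / n_tissue
        if (frac >= ecm_fraction - tol) break
      }
    }
    if (abs(frac - ecm_fraction) > tol)
      stop("ecm_fraction ", ecm_fraction,
           " unreachable within 0.005 at size ", size)
  }

  img <- array(1, dim = c(size, size, 3))  # white background
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[tissue] <- myocyte_rgb[ch]
    plane[ecm] <- ecm_rgb[ch]
    noise <- matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
    plane[tissue] <- plane[tissue] + noise[tissue]
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  list(image = img, ecm_mask = ecm, tissue_mask = tissue,
       ecm_fraction = sum(ecm) / n_tissue)
}

#' Generate a multi-tissue expression panel
#'
#' Long-format panel of expression values (RPKM-like scale) across tissues,
#' with one designated feature enriched in one tissue at `enrichment_fold`
#' times the baseline mean of all other tissues; every other feature is
#' uniform across tissues. Used to validate the SPM tissue-specificity score.
#'
#' @param n_tissues Number of tissues (>= 2); default 24, an LV plus 23
#'   comparison tissues.
#' @param samples_per_tissue Samples per tissue.
#' @param enriched_feature Id of the enriched feature.
#' @param enrichment_fold Mean fold enrichment in the designated tissue
#'   (>= 1; 1 = no enrichment).
#' @param enriched_tissue Name of the designated tissue (default `"LV"`).
#' @param n_background Number of additional uniform features.
#' @param cv Log-normal coefficient of variation of sample noise.
#' @param seed Integer seed.
#' @return Data frame (`feature`, `tissue`, `sample`, `value`) of class
#'   `TissuePanel`.
#' @export
generate_tissue_panel <- function(n_tissues = 24, samples_per_tissue = 10,
                                  enriched_feature = "miR-LV",
                                  enrichment_fold = 8,
                                  enriched_tissue = "LV",
                                  n_background = 5, cv = 0.3, seed = 1L) {
  if (n_tissues < 2) stop("n_tissues must be >= 2")
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  set.seed(seed)
  tissues <- c(enriched_tissue,
               sprintf("tissue%02d", seq_len(n_tissues - 1)))
  feats <- c(enriched_feature, sprintf("feat%02d", seq_len(n_background)))
  base_mu <- c(100, stats::runif(n_background, 50, 200))
  sdlog <- sqrt(log(1 + cv^2))
  rows <- list()
  for (f in seq_along(feats)) for (tt in seq_along(tissues)) {
    mu <- base_mu[f]
    if (f == 1 && tt == 1) mu <- mu * enrichment_fold
    vals <- stats::rlnorm(samples_per_tissue, log(mu) - sdlog^2 / 2, sdlog)
    rows[[length(rows) + 1]] <- data.frame(
      feature = feats[f], tissue = tissues[tt],
      sample = sprintf("%s_%02d", tissues[tt], seq_len(samples_per_tissue)),
      value = vals, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- unique(c("TissuePanel", class(out)))
  out
}
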