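#' Quantize an image to L gray levels
#'
#' Linear binning into L equal-width bins labelled `0 .. L-1`. By default
#' the occupied intensity range `[min, max]` of the image is binned (a
#' constant image maps entirely to level 0); passing a fixed `range` bins
#' that interval instead, which makes quantized values comparable across
#' images.
#'
#' @param image a [gray_image] or integer matrix.
#' @param levels target number of levels L (>= 2).
#' @param range optional fixed `c(lo, hi)` intensity range to bin.
#' @return a [gray_image] with `levels = L`.
#' @export
quantize <- function(image, levels = 8L, range = NULL) {
  if (levels < 2) stop("levels must be >= 2")
  m <- as_gray_matrix(image)
  if (is.null(range)) {
    lo <- min(m); hi <- max(m)
  } else {
    lo <- range[1]; hi <- range[2]
    m <- pmin(pmax(m, lo), hi)
  }
  q <- if (hi == lo) {
    matrix(0L, nrow(m), ncol(m))
  } else {
    pmin(as.integer(floor((m - lo) / (hi - lo) * levels)), levels - 1L)
  }
  gray_image(matrix(q, nrow(m), ncol(m)), levels = levels)
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of pixel values at positions `p` and `p + offset` (offset in
#' `(row_shift, col_shift)` units). In symmetric mode each pair is counted
#' in both directions (the transpose is added); in normalised mode the
#' matrix is divided by the total pair count so entries sum to 1.
#'
#' @param image quantized [gray_image] with values in `0 .. levels-1`.
#' @param offset integer `c(row_shift, col_shift)`.
#' @param levels number of gray levels L.
#' @param symmetric logical (default TRUE).
#' @param normalize logical (default TRUE).
#' @return an L x L matrix with attributes `offset`, `symmetric`,
#'   `normalized`, `counts_total`.
#' @export
compute_glcm <- function(image, offset = c(0L, 1L), levels = img_levels(image),
                         symmetric = TRUE, normalize = TRUE) {
  m <- as_gray_matrix(image)
  dr <- offset[1]; dc <- offset[2]
  if (abs(dr) >= nrow(m) || abs(dc) >= ncol(m)) {
    stop("invalid parameter: offset magnitude >= image dimension")
  }
  if (any(m > levels - 1)) stop("image not quantized to the stated levels")
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  r1 <- rows[rows + dr >= 1 & rows + dr <= nrow(m)]
  c1 <- cols[cols + dc >= 1 & cols + dc <= ncol(m)]
  a <- m[r1, c1, drop = FALSE]
  b <- m[r1 + dr, c1 + dc, drop = FALSE]
  P <- matrix(tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                       nbins = levels * levels),
              levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  total <- sum(P)
  if (normalize && total > 0) P <- P / total
  structure(P, offset = as.integer(offset), symmetric = symmetric,
            normalized = normalize, counts_total = total)
}

#' Haralick-style texture features of a normalised GLCM
#'
#' Six classical co-occurrence statistics: contrast, dissimilarity, energy
#' (angular second moment), homogeneity (inverse difference moment),
#' entropy (base-2, with 0 log 0 := 0) and correlation (0 when either
#' marginal SD is 0).
#'
#' @param glcm normalised L x L co-occurrence matrix.
#' @return named numeric vector of the six features.
#' @export
haralick_features <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-6) stop("contract violation: GLCM must be normalized")
  L <- nrow(glcm)
  i <- matrix(seq_len(L) - 1, L, L)
  j <- t(i)
  p <- glcm
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  pe <- p[p > 0]
  corr <- if (s_i == 0 || s_j == 0) 0 else sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  c(contrast      = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    energy        = sum(p^2),
    homogeneity   = sum(p / (1 + (i - j)^2)),
    entropy       = -sum(pe * log2(pe)),
    correlation   = corr)
}

#' Split an image into anatomical half-planes
#'
#' On a 2-D slice the coronal split is realised as top/bottom halves and the
#' sagittal split as left/right halves. Odd dimensions give the extra
#' row/column to the first half.
#'
#' @param image a [gray_image].
#' @return named list `top`, `bottom`, `left`, `right` of [gray_image]s.
#' @export
split_planes <- function(image) {
  m <- as_gray_matrix(image)
  if (nrow(m) < 2 || ncol(m) < 2) stop("image must be at least 2 x 2")
  lv <- img_levels(image)
  rh <- ceiling(nrow(m) / 2); ch <- ceiling(ncol(m) / 2)
  list(top    = gray_image(m[seq_len(rh), , drop = FALSE], lv),
       bottom = gray_image(m[(rh + 1):nrow(m), , drop = FALSE], lv),
       left   = gray_image(m[, seq_len(ch), drop = FALSE], lv),
       right  = gray_image(m[, (ch + 1):ncol(m), drop = FALSE], lv))
}

# Offsets for GLCM angles 0, 45, 90, 135 degrees at unit distance
# (row shift, col shift), skimage convention.
glcm_offsets_default <- function() {
  list(deg0 = c(0L, 1L), deg45 = c(-1L, 1L), deg90 = c(-1L, 0L),
       deg135 = c(-1L, -1L))
}

#' Regional GLCM texture feature vector
#'
#' Quantizes the image over its full representable range (`0 .. levels-1`
#' of the input, so features are comparable across images of one cohort),
#' then for each region (whole image plus the four
#' half-planes by default) and each offset (unit distance at 0/45/90/135
#' degrees) computes a symmetric normalised GLCM and its six Haralick
#' features, concatenated in a fixed documented order:
#' region (whole, top, bottom, left, right) slowest, then offset, then
#' feature. Default layout length: 5 x 4 x 6 = 120. A region too small for
#' an offset contributes zeros with a warning.
#'
#' @param image a [gray_image].
#' @param levels quantization levels (default 8).
#' @param offsets list of `c(row_shift, col_shift)` offsets.
#' @param regions `"whole+halves"` (default) or `"whole"`.
#' @return named numeric vector; names encode `region.offset.feature`.
#' @export
extract_feature_vector <- function(image, levels = 8L,
                                   offsets = glcm_offsets_default(),
                                   regions = c("whole+halves", "whole")) {
  regions <- match.arg(regions)
  q <- quantize(image, levels, range = c(0, img_levels(image) - 1))
  regs <- list(whole = q)
  if (regions == "whole+halves") regs <- c(regs, split_planes(q))
  feat_names <- c("contrast", "dissimilarity", "energy", "homogeneity",
                  "entropy", "correlation")
  if (is.null(names(offsets))) names(offsets) <- paste0("off", seq_along(offsets))
  out <- numeric(0)
  for (rn in names(regs)) {
    for (on in names(offsets)) {
      off <- offsets[[on]]
      sub <- as_gray_matrix(regs[[rn]])
      vals <- if (abs(off[1]) >= nrow(sub) || abs(off[2]) >= ncol(sub)) {
        warning(sprintf("region '%s' smaller than offset (%d,%d); features set to 0",
                        rn, off[1], off[2]))
        stats::setNames(numeric(6), feat_names)
      } else {
        haralick_features(compute_glcm(regs[[rn]], off, levels))
      }
      names(vals) <- paste(rn, on, feat_names, sep = ".")
      out <- c(out, vals)
    }
  }
  out
}
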