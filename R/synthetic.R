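#' Generate a brain-like phantom image
#'
#' A deterministic, seeded stand-in for a clinical MRI slice: an elliptical
#' "head" of tissue-A (gray 100) on dark background (gray 10), containing a
#' few blobs of tissue-B (gray 170) and, optionally, one irregular bright
#' tumour blob (gray 230) with radius 5-15% of the image size. Noise is
#' applied last. The geometry and gray levels are chosen so that impulse
#' noise measurably hurts plain FCM segmentation and tumour presence is
#' detectable from co-occurrence texture — the two properties the pipeline
#' is designed to exploit.
#'
#' @param size image side length (>= 32).
#' @param tumor logical; include a tumour blob.
#' @param noise one of `"none"`, `"gaussian"`, `"salt_pepper"`, `"speckle"`.
#' @param level noise level in `[0, 0.5]`: SD fraction of the 0-255 range
#'   (gaussian), corrupted-pixel fraction (salt & pepper), multiplicative
#'   SD (speckle).
#' @param seed integer seed; the phantom is a pure function of its
#'   arguments.
#' @return list of class `phantom`: `image` ([gray_image]), `truth`
#'   (integer matrix, 0 background / 1 tissue-A / 2 tissue-B / 3 tumour),
#'   `meta`.
#' @export
generate_phantom <- function(size = 128L, tumor = FALSE,
                             noise = c("none", "gaussian", "salt_pepper", "speckle"),
                             level = 0.05, seed = 1L) {
  noise <- tryCatch(match.arg(noise), error = function(e)
    stop("invalid noise kind; supported: none, gaussian, salt_pepper, speckle"))
  if (size < 32) stop("size must be >= 32")
  if (level < 0 || level > 0.5) stop("level must lie in [0, 0.5]")
  grays <- c(10L, 100L, 170L, 230L)
  run_seeded(seed, {
    cx <- (size + 1) / 2
    r <- matrix(seq_len(size), size, size)
    cc <- t(r)
    a <- 0.42 * size; b <- 0.36 * size
    head <- ((r - cx) / a)^2 + ((cc - cx) / b)^2 <= 1
    truth <- matrix(0L, size, size)
    truth[head] <- 1L
    # tissue-B blobs inside the head
    for (k in seq_len(3L)) {
      bc <- cx + c(stats::runif(1, -0.55, 0.55) * a, stats::runif(1, -0.55, 0.55) * b)
      ba <- stats::runif(1, 0.05, 0.12) * size
      bb <- stats::runif(1, 0.05, 0.12) * size
      blob <- ((r - bc[1]) / ba)^2 + ((cc - bc[2]) / bb)^2 <= 1
      truth[blob & head] <- 2L
    }
    tumor_meta <- NULL
    if (tumor) {
      tc <- cx + c(stats::runif(1, -0.4, 0.4) * a, stats::runif(1, -0.4, 0.4) * b)
      r0 <- stats::runif(1, 0.05, 0.15) * size
      ph <- stats::runif(2, 0, 2 * pi)
      theta <- atan2(cc - tc[2], r - tc[1])
      rad <- sqrt((r - tc[1])^2 + (cc - tc[2])^2)
      edge <- r0 * (1 + 0.2 * sin(3 * theta + ph[1]) + 0.1 * sin(5 * theta + ph[2]))
      truth[rad <= edge & head] <- 3L
      tumor_meta <- list(center = tc, radius = r0)
    }
    img <- matrix(grays[truth + 1L], size, size)
    img <- apply_noise(img, noise, level)
    structure(list(image = gray_image(img, 256L), truth = truth,
                   meta = list(seed = seed, noise = noise, level = level,
                               tumor = tumor, tumor_geom = tumor_meta)),
              class = "phantom")
  })
}

apply_noise <- function(img, noise, level) {
  n <- length(img)
  out <- switch(noise,
    none = img,
    gaussian = img + stats::rnorm(n, 0, level * 255),
    salt_pepper = {
      hit <- stats::runif(n) < level
      salt <- stats::runif(n) < 0.5
      x <- img
      x[hit & salt] <- 255
      x[hit & !salt] <- 0
      x
    },
    speckle = img * (1 + stats::rnorm(n, 0, level)))
  matrix(pmin(pmax(round(out), 0), 255), nrow(img), ncol(img))
}

#' Generate a labelled tumour / non-tumour phantom set
#'
#' `n_tumor` tumour-present and `n_clean` tumour-absent phantoms with
#' distinct derived seeds, shuffled deterministically. Labels: 1 tumour,
#' 0 clean.
#'
#' @param n_tumor,n_clean counts (>= 1).
#' @param size phantom side length.
#' @param noise,level noise settings (see [generate_phantom]); default
#'   gaussian at level 0.05.
#' @param seed master seed; every phantom seed derives from it.
#' @return list `phantoms` (list of [generate_phantom] results) and
#'   `labels` (0/1 vector).
#' @export
generate_classification_set <- function(n_tumor, n_clean, size = 64L,
                                        noise = "gaussian", level = 0.05,
                                        seed = 1L) {
  stopifnot(n_tumor >= 1, n_clean >= 1)
  n <- n_tumor + n_clean
  plan <- run_seeded(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    ord <- sample.int(n)
    list(seeds = seeds, ord = ord)
  })
  labels <- c(rep(1L, n_tumor), rep(0L, n_clean))[plan$ord]
  phantoms <- lapply(seq_len(n), function(i) {
    generate_phantom(size = size, tumor = labels[i] == 1L, noise = noise,
                     level = level, seed = plan$seeds[i])
  })
  list(phantoms = phantoms, labels = labels)
}

#' Texture feature table for a phantom set
#'
#' Applies [extract_feature_vector] to every phantom image and stacks the
#' results into a matrix (one row per phantom).
#'
#' @param set output of [generate_classification_set].
#' @param ... passed to [extract_feature_vector].
#' @return numeric matrix with feature-name columns.
#' @export
phantom_features <- function(set, ...) {
  rows <- lapply(set$phantoms, function(ph) extract_feature_vector(ph$image, ...))
  do.call(rbind, rows)
}
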