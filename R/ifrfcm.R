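#' Configuration for IFRFCM segmentation
#'
#' Collects every tunable of the improved fast-and-robust fuzzy C-means
#' segmenter. Defaults follow common FLICM/FRFCM practice: fuzziness 2,
#' 3x3 spatial neighbourhood, disk radius 1 reconstruction, 3x3 Wiener
#' window, convergence at 1e-4 gray levels of centroid movement.
#'
#' @param clusters number of clusters C (>= 1).
#' @param fuzziness fuzzifier v (> 1); the membership update is undefined
#'   at v = 1.
#' @param alpha multiplicative scale on the neighbourhood fuzzy factor in
#'   `(0, 1]`; `alpha = 0` disables it (plain FCM limit).
#' @param radius half-width of the square spatial neighbourhood N_p used by
#'   the fuzzy factor (0 disables the neighbourhood sum).
#' @param recon_radius disk radius for morphological reconstruction.
#' @param reconstruct logical; run reconstruction preprocessing.
#' @param wiener logical; Wiener-filter the membership planes.
#' @param wiener_window odd window size >= 3 for the adaptive Wiener filter.
#' @param max_iter maximum alternating-update iterations.
#' @param tol convergence threshold on the max absolute centroid change
#'   (gray-level units).
#' @param seed integer seed for centroid initialisation (NULL = current RNG).
#' @param init_centroids optional explicit initial centroids (overrides the
#'   seeded quantile initialisation).
#' @return a list of class `cluster_config`.
#' @export
cluster_config <- function(clusters, fuzziness = 2, alpha = 1, radius = 1L,
                           recon_radius = 1L, reconstruct = TRUE,
                           wiener = TRUE, wiener_window = 3L,
                           max_iter = 100L, tol = 1e-4, seed = NULL,
                           init_centroids = NULL) {
  if (clusters < 1) stop("clusters must be >= 1")
  if (fuzziness <= 1) stop("fuzziness must be > 1")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (wiener_window %% 2 != 1 || wiener_window < 3) {
    stop("wiener_window must be odd and >= 3")
  }
  structure(list(clusters = as.integer(clusters), fuzziness = fuzziness,
                 alpha = alpha, radius = as.integer(radius),
                 recon_radius = as.integer(recon_radius),
                 reconstruct = isTRUE(reconstruct), wiener = isTRUE(wiener),
                 wiener_window = as.integer(wiener_window),
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 init_centroids = init_centroids),
            class = "cluster_config")
}

#' Fuzzy membership partition matrix
#'
#' The C x h matrix S of memberships of each gray level in each cluster,
#' together with the cluster centroids (gray-value units). Each gray-level
#' column sums to 1.
#'
#' @param S C x h membership matrix.
#' @param centroids length-C centroid vector.
#' @return object of class `membership_matrix`.
#' @export
membership_matrix <- function(S, centroids) {
  stopifnot(nrow(S) == length(centroids))
  if (any(S < -1e-12) || any(S > 1 + 1e-12)) stop("memberships must lie in [0, 1]")
  structure(list(S = S, centroids = as.numeric(centroids)),
            class = "membership_matrix")
}

run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Neighbourhood fuzzy factor at one pixel
#'
#' The spatial penalty G_pq pulling a pixel's membership toward its
#' neighbours': a sum over the neighbourhood of
#' `1/(d_pr + 1) * (1 - sigma_qr)^v * (x_r - p_q)^2`, where `d_pr` is the
#' Euclidean distance between pixel centres, `sigma_qr` the neighbour's
#' membership in cluster q (looked up from the gray-level partition matrix)
#' and `p_q` the cluster centroid.
#'
#' @param memberships a [membership_matrix].
#' @param image the (reconstructed) [gray_image] supplying neighbour values.
#' @param config a [cluster_config] (uses `radius` and `fuzziness`).
#' @param pixel integer `c(row, col)`, 1-based.
#' @param cluster cluster index, 1-based.
#' @return a non-negative scalar; 0 when `radius` is 0.
#' @export
fuzzy_factor <- function(memberships, image, config, pixel, cluster) {
  m <- as_gray_matrix(image)
  nr <- nrow(m); nc <- ncol(m)
  i <- pixel[1]; j <- pixel[2]
  if (i < 1 || i > nr || j < 1 || j > nc) stop("pixel outside image")
  if (cluster < 1 || cluster > nrow(memberships$S)) stop("cluster index out of range")
  R <- config$radius
  if (R == 0) return(0)
  pq <- memberships$centroids[cluster]
  v <- config$fuzziness
  g <- 0
  for (dr in -R:R) for (dc in -R:R) {
    if (dr == 0 && dc == 0) next
    r <- i + dr; cc <- j + dc
    if (r < 1 || r > nr || cc < 1 || cc > nc) next
    d <- sqrt(dr^2 + dc^2)
    sig <- memberships$S[cluster, m[r, cc] + 1L]
    g <- g + (1 / (d + 1)) * (1 - sig)^v * (m[r, cc] - pq)^2
  }
  g
}

# Vectorised fuzzy factor aggregated into the gray-level (histogram) domain:
# per-pixel G_pq is computed on the reconstructed image, then averaged over
# the pixels carrying each gray level. Returns a C x h matrix (0 where a
# gray level has no pixels).
fuzzy_factor_histogram <- function(S, centroids, image, config) {
  m <- as_gray_matrix(image)
  h <- ncol(S); C <- nrow(S)
  R <- config$radius
  v <- config$fuzziness
  Gbar <- matrix(0, C, h)
  if (R == 0) return(Gbar)
  idx <- as.integer(m) + 1L
  counts <- tabulate(idx, nbins = h)
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  w <- 1 / (sqrt(offs$dr^2 + offs$dc^2) + 1)
  for (q in seq_len(C)) {
    sig_plane <- matrix(S[q, idx], nrow(m), ncol(m))
    contrib <- (1 - sig_plane)^v * (m - centroids[q])^2
    G <- matrix(0, nrow(m), ncol(m))
    for (k in seq_len(nrow(offs))) {
      G <- G + w[k] * shift_matrix(contrib, -offs$dr[k], -offs$dc[k], fill = 0)
    }
    sums <- rowsum(as.vector(G), idx)
    z <- as.integer(rownames(sums))
    Gbar[q, z] <- sums / counts[z]
  }
  Gbar
}

#' Membership update of histogram-domain FCM
#'
#' Standard Lagrangian minimiser of the fuzzified objective with the fuzzy
#' factor held fixed: `sigma_qz` proportional to
#' `(d_qz^2 + G_qz)^(-1/(v-1))`, normalised per gray level. Gray levels at
#' zero distance to one or more centroids (with zero factor) split their
#' membership equally among those clusters.
#'
#' @param centroids length-C centroid vector.
#' @param histogram length-h gray-level counts (used only for dimension
#'   here; zero-count levels still receive memberships).
#' @param config a [cluster_config].
#' @param Gbar optional C x h fuzzy-factor matrix (NULL = zero).
#' @return a C x h membership matrix whose columns each sum to 1.
#' @export
update_memberships <- function(centroids, histogram, config, Gbar = NULL) {
  C <- length(centroids)
  h <- length(histogram)
  vals <- seq_len(h) - 1
  D <- outer(centroids, vals, function(p, z) (z - p)^2)
  if (!is.null(Gbar) && config$alpha > 0) D <- D + config$alpha * Gbar
  if (C == 1L) return(matrix(1, 1, h))
  e <- 1 / (config$fuzziness - 1)
  S <- matrix(0, C, h)
  zero_cols <- which(apply(D, 2, function(d) any(d == 0)))
  ok_cols <- setdiff(seq_len(h), zero_cols)
  if (length(ok_cols)) {
    Dm <- D[, ok_cols, drop = FALSE]^(-e)
    S[, ok_cols] <- sweep(Dm, 2, colSums(Dm), "/")
  }
  for (z in zero_cols) {
    zn <- D[, z] == 0
    S[zn, z] <- 1 / sum(zn)
  }
  S
}

#' Centroid update of histogram-domain FCM
#'
#' Count-weighted fuzzy mean of the gray levels:
#' `p_q = sum_z counts_z sigma_qz^v xi_z / sum_z counts_z sigma_qz^v`.
#' A starved cluster (zero denominator) is reinitialised to the modal gray
#' level with a warning.
#'
#' @param S C x h membership matrix.
#' @param histogram length-h counts.
#' @param values per-gray-level representative values (default `0:(h-1)`).
#' @param config a [cluster_config].
#' @return length-C centroid vector within the occupied gray range.
#' @export
update_centroids <- function(S, histogram, values = seq_along(histogram) - 1,
                             config) {
  if (sum(histogram) < 1) stop("histogram has no pixels")
  Sv <- S^config$fuzziness
  den <- as.vector(Sv %*% histogram)
  num <- as.vector(Sv %*% (histogram * values))
  cent <- num / den
  starved <- !is.finite(cent) | den == 0
  if (any(starved)) {
    warning(sprintf("%d starved cluster(s) reinitialised to the modal gray level",
                    sum(starved)))
    cent[starved] <- values[which.max(histogram)]
  }
  cent
}

#' Clustering objective on the gray-level histogram
#'
#' `J0 = sum_q sum_z counts_z sigma_qz^v (xi_z - p_q)^2 + sum_q sum_z G_qz`.
#'
#' @inheritParams update_centroids
#' @param centroids length-C centroid vector.
#' @param Gbar optional C x h fuzzy-factor matrix (NULL = zero).
#' @return non-negative scalar.
#' @export
fcm_objective <- function(S, centroids, histogram,
                          values = seq_along(histogram) - 1, config,
                          Gbar = NULL) {
  D <- outer(centroids, values, function(p, z) (z - p)^2)
  J <- sum(t(S^config$fuzziness * D) * histogram)
  if (!is.null(Gbar) && config$alpha > 0) J <- J + config$alpha * sum(Gbar)
  J
}

wiener_plane <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- box_count(nrow(x), ncol(x), half)
  m <- box_sum(x, half) / n
  v <- pmax(box_sum(x^2, half) / n - m^2, 0)
  noise <- mean(v)
  gain <- ifelse(v > noise, (v - noise) / v, 0)
  m + gain * (x - m)
}

#' Adaptive Wiener filtering of the membership matrix
#'
#' Expands the gray-level partition matrix to the pixel grid (each pixel
#' takes the membership of its gray value), smooths each cluster's
#' membership plane with a local adaptive Wiener filter (windowed mean and
#' variance; noise power estimated as the mean local variance), and
#' renormalises so each pixel's memberships across clusters sum to 1.
#'
#' @param memberships a [membership_matrix] (or plain C x h matrix).
#' @param image the [gray_image] giving the gray-to-pixel map.
#' @param window odd window size >= 3.
#' @return a 3-d array `[rows, cols, clusters]` of filtered memberships.
#' @export
wiener_filter_membership <- function(memberships, image, window = 3L) {
  S <- if (inherits(memberships, "membership_matrix")) memberships$S else memberships
  m <- as_gray_matrix(image)
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (window > min(dim(m))) stop("invalid parameter: window exceeds image dimension")
  C <- nrow(S)
  idx <- as.integer(m) + 1L
  out <- array(0, c(nrow(m), ncol(m), C))
  for (q in seq_len(C)) {
    plane <- matrix(S[q, idx], nrow(m), ncol(m))
    out[, , q] <- wiener_plane(plane, window)
  }
  tot <- apply(out, c(1, 2), sum)
  for (q in seq_len(C)) {
    plane <- out[, , q]
    plane <- ifelse(tot > 0, plane / tot, 1 / C)
    out[, , q] <- plane
  }
  out
}

# Evenly spaced centroids over the occupied gray range, jittered by seeded
# noise. Spreading over the range (rather than distribution quantiles)
# avoids collapsing several centroids onto a dominant class such as the
# image background.
init_centroids_spread <- function(pixels, C, seed) {
  lo <- min(pixels); hi <- max(pixels)
  base <- lo + (seq_len(C) - 0.5) / C * (hi - lo)
  jit <- run_seeded(seed, stats::runif(C, -0.5, 0.5))
  sort(base + jit)
}

#' Segment a grayscale image with IFRFCM
#'
#' Full pipeline: morphological reconstruction, gray-level histogram,
#' alternating membership/centroid updates with the neighbourhood fuzzy
#' factor, adaptive Wiener filtering of the membership planes, and
#' defuzzification to a per-pixel label map (argmax; ties to the lowest
#' cluster index). Setting `reconstruct = FALSE`, `alpha = 0`,
#' `wiener = FALSE` in the config recovers plain histogram FCM.
#'
#' @param image a [gray_image].
#' @param config a [cluster_config].
#' @return a list of class `ifrfcm_result`: `labels` (0-based integer
#'   matrix), `memberships` (pixel-domain array), `memberships_gray`
#'   ([membership_matrix]), `centroids`, `objective_trace`, `n_iter`,
#'   `converged`, `config`.
#' @export
ifrfcm_segment <- function(image, config) {
  stopifnot(inherits(config, "cluster_config"))
  recon <- if (config$reconstruct) {
    morphological_reconstruct(image, config$recon_radius)
  } else image
  counts <- compute_gray_histogram(recon)
  h <- length(counts)
  vals <- seq_len(h) - 1
  pix <- as_gray_matrix(recon)
  C <- config$clusters

  centroids <- if (!is.null(config$init_centroids)) {
    as.numeric(config$init_centroids)
  } else {
    init_centroids_spread(as.vector(pix), C, config$seed)
  }
  S <- update_memberships(centroids, counts, config, Gbar = NULL)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    Gbar <- if (config$alpha > 0 && config$radius > 0) {
      fuzzy_factor_histogram(S, centroids, recon, config)
    } else NULL
    S <- update_memberships(centroids, counts, config, Gbar = Gbar)
    new_cent <- update_centroids(S, counts, vals, config)
    trace <- c(trace, fcm_objective(S, new_cent, counts, vals, config, Gbar = Gbar))
    delta <- max(abs(new_cent - centroids))
    centroids <- new_cent
    if (delta < config$tol) { converged <- TRUE; break }
  }

  mm <- membership_matrix(S, centroids)
  planes <- if (config$wiener) {
    wiener_filter_membership(mm, recon, config$wiener_window)
  } else {
    idx <- as.integer(pix) + 1L
    arr <- array(0, c(nrow(pix), ncol(pix), C))
    for (q in seq_len(C)) arr[, , q] <- matrix(S[q, idx], nrow(pix), ncol(pix))
    arr
  }
  flat <- matrix(planes, nrow = nrow(pix) * ncol(pix), ncol = C)
  labels <- matrix(max.col(flat, ties.method = "first") - 1L,
                   nrow(pix), ncol(pix))
  structure(list(labels = labels, memberships = planes,
                 memberships_gray = mm, centroids = centroids,
                 objective_trace = trace, n_iter = iter,
                 converged = converged, config = config),
            class = "ifrfcm_result")
}

#' @export
print.ifrfcm_result <- function(x, ...) {
  cat(sprintf("<ifrfcm_result: %d clusters, %d iterations (%s), centroids %s>\n",
              x$config$clusters, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              paste(round(x$centroids, 2), collapse = ", ")))
  invisible(x)
}

#' Permutation-matched segmentation accuracy
#'
#' Pixel accuracy of a label map against ground truth, maximised over all
#' assignments of predicted clusters to truth classes, so the score is
#' invariant to cluster relabelling.
#'
#' @param labels predicted integer label matrix.
#' @param truth ground-truth integer label matrix of the same shape.
#' @return accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(labels, truth) {
  stopifnot(all(dim(labels) == dim(truth)))
  lp <- sort(unique(as.vector(labels)))
  lt <- sort(unique(as.vector(truth)))
  tab <- table(factor(labels, levels = lp), factor(truth, levels = lt))
  k <- max(length(lp), length(lt))
  M <- matrix(0, k, k)
  M[seq_along(lp), seq_along(lt)] <- tab
  perms <- all_permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    hit <- sum(M[cbind(seq_len(k), perms[i, ])])
    if (hit > best) best <- hit
  }
  best / length(labels)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), k)
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
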