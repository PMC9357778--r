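test_that("fuzzy factor vanishes in the trivial cases and matches a direct sum", {
  img <- random_gray(5, 5, 8)
  cfg <- cluster_config(clusters = 2, fuzziness = 2, radius = 1)

  # full membership of the queried cluster for every gray level -> G = 0
  mm <- membership_matrix(rbind(rep(1, 8), rep(0, 8)), c(3, 5))
  expect_equal(fuzzy_factor(mm, img, cfg, c(3, 3), 1), 0)

  # all neighbour values at the centroid -> zero squared distance
  flat <- gray_image(matrix(4L, 5, 5), 8L)
  mm2 <- membership_matrix(rbind(rep(0.5, 8), rep(0.5, 8)), c(4, 6))
  expect_equal(fuzzy_factor(mm2, flat, cfg, c(2, 2), 1), 0)

  # radius 0 -> no neighbourhood
  cfg0 <- cluster_config(clusters = 2, radius = 0)
  expect_equal(fuzzy_factor(mm2, img, cfg0, c(2, 2), 2), 0)

  # 3x3 hand case against an explicit sum over the 8 neighbours
  set.seed(21)
  m3 <- random_gray(3, 3, 8)
  S <- matrix(runif(16), 2, 8)
  S <- sweep(S, 2, colSums(S), "/")
  mm3 <- membership_matrix(S, c(2.5, 5.5))
  got <- fuzzy_factor(mm3, m3, cfg, c(2, 2), 1)
  want <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    xr <- unclass(m3)[2 + dr, 2 + dc]
    want <- want + 1 / (sqrt(dr^2 + dc^2) + 1) *
      (1 - S[1, xr + 1])^2 * (xr - 2.5)^2
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("membership update normalizes, handles C=1, midpoints and exact ties", {
  hist3 <- c(4L, 0L, 6L)
  cfg <- cluster_config(clusters = 1, fuzziness = 2, alpha = 0)
  expect_equal(update_memberships(5, rep(1L, 10), cfg), matrix(1, 1, 10))

  # gray value midway between two centroids at v = 2 -> 0.5 / 0.5
  cfg2 <- cluster_config(clusters = 2, fuzziness = 2, alpha = 0)
  S <- update_memberships(c(0, 2), hist3, cfg2)
  expect_equal(S[, 2], c(0.5, 0.5))
  expect_equal(colSums(S), rep(1, 3))

  # centroid exactly on a gray level -> crisp column
  expect_equal(S[, 1], c(1, 0))

  # tie: two centroids on the same gray level split equally
  S2 <- update_memberships(c(1, 1, 4), c(2L, 3L, 1L, 0L, 1L), cfg2)
  expect_equal(S2[, 2], c(0.5, 0.5, 0))
})

test_that("membership update minimizes the objective (simplex grid oracle)", {
  # 3 gray levels, C=2, v=2, G=0: compare against grid search over the
  # per-column membership simplex
  counts <- c(3L, 5L, 2L)
  cent <- c(0.4, 1.7)
  cfg <- cluster_config(clusters = 2, fuzziness = 2, alpha = 0)
  S <- update_memberships(cent, counts, cfg)
  vals <- 0:2
  for (z in 1:3) {
    col_obj <- function(u) {
      counts[z] * (u^2 * (vals[z] - cent[1])^2 + (1 - u)^2 * (vals[z] - cent[2])^2)
    }
    grid <- seq(0, 1, by = 1e-4)
    best <- grid[which.min(vapply(grid, col_obj, numeric(1)))]
    expect_lt(abs(S[1, z] - best), 1e-3)
  }
})

test_that("centroid update is the count-weighted fuzzy mean with starvation fallback", {
  cfg <- cluster_config(clusters = 1, fuzziness = 2)
  counts <- c(2L, 0L, 6L, 2L)
  S1 <- matrix(1, 1, 4)
  expect_equal(update_centroids(S1, counts, config = cfg),
               sum(counts * 0:3) / sum(counts))

  # symmetric histogram + symmetric memberships -> midpoint
  cfg2 <- cluster_config(clusters = 2, fuzziness = 2)
  Ssym <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(update_centroids(Ssym, c(5L, 5L), config = cfg2), c(0.5, 0.5))

  # random instance against a direct weighted-sum loop
  set.seed(31)
  S <- matrix(runif(12), 3, 4)
  S <- sweep(S, 2, colSums(S), "/")
  got <- update_centroids(S, counts, config = cfg2)
  for (q in 1:3) {
    want <- sum(counts * S[q, ]^2 * 0:3) / sum(counts * S[q, ]^2)
    expect_equal(got[q], want, tolerance = 1e-12)
  }

  # starved cluster snaps to the modal gray level
  Sstarve <- rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_warning(cs <- update_centroids(Sstarve, counts, config = cfg2), "starved")
  expect_equal(cs[2], 2)
})

test_that("objective is exact on a hand case and zero at a perfect fit", {
  cfg <- cluster_config(clusters = 2, fuzziness = 2, alpha = 0)
  counts <- c(4L, 0L, 6L)
  # perfect: crisp memberships, centroids on the occupied levels
  Sperf <- rbind(c(1, 0.5, 0), c(0, 0.5, 1))
  expect_equal(fcm_objective(Sperf, c(0, 2), counts, config = cfg), 0)

  set.seed(41)
  S <- matrix(runif(6), 2, 3); S <- sweep(S, 2, colSums(S), "/")
  cent <- c(0.3, 1.8)
  want <- 0
  for (q in 1:2) for (z in 1:3) {
    want <- want + counts[z] * S[q, z]^2 * ((z - 1) - cent[q])^2
  }
  expect_equal(fcm_objective(S, cent, counts, config = cfg), want, tolerance = 1e-12)
})

test_that("Wiener filtering matches the per-pixel oracle and renormalizes", {
  # constant plane is untouched
  S <- rbind(rep(0.3, 8), rep(0.7, 8))
  img <- gray_image(matrix(3L, 6, 6), 8L)
  out <- wiener_filter_membership(S, img, 3)
  expect_equal(out[, , 1], matrix(0.3, 6, 6))

  # impulse in a flat plane: compare against the sliding-window oracle
  m <- matrix(2L, 7, 7); m[4, 4] <- 5L
  img2 <- gray_image(m, 8L)
  S2 <- matrix(0, 2, 8)
  S2[1, ] <- c(0, 0, 1, 0, 0, 0.2, 0, 0)
  S2[2, ] <- 1 - S2[1, ]
  out2 <- wiener_filter_membership(S2, img2, 3)
  plane1 <- matrix(S2[1, unclass(img2) + 1], 7, 7)
  plane2 <- matrix(S2[2, unclass(img2) + 1], 7, 7)
  f1 <- naive_wiener(plane1, 3); f2 <- naive_wiener(plane2, 3)
  tot <- f1 + f2
  expect_equal(out2[, , 1], ifelse(tot > 0, f1 / tot, 0.5), tolerance = 1e-12)

  # per-pixel normalization across clusters
  sums <- apply(out2, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  expect_error(wiener_filter_membership(S2, img2, 9), "window")
  expect_error(wiener_filter_membership(S2, img2, 4), "odd")
})

test_that("segmentation recovers a noiseless two-level image and is label-permutation safe", {
  m <- matrix(20L, 16, 16)
  m[, 9:16] <- 200L
  img <- gray_image(m)
  res <- ifrfcm_segment(img, cluster_config(clusters = 2, seed = 5))
  truth <- matrix(0L, 16, 16); truth[, 9:16] <- 1L
  expect_equal(label_accuracy(res$labels, truth), 1)
  # permuting predicted labels changes nothing
  expect_equal(label_accuracy(1L - res$labels, truth), 1)
  expect_true(all(res$labels %in% 0:1))
  expect_length(res$objective_trace, res$n_iter)
})

test_that("segmentation is deterministic given the seed and flags non-convergence", {
  ph <- generate_phantom(48, tumor = FALSE, noise = "gaussian", level = 0.04, seed = 2)
  cfg <- cluster_config(clusters = 3, seed = 9)
  r1 <- ifrfcm_segment(ph$image, cfg)
  r2 <- ifrfcm_segment(ph$image, cfg)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$centroids, r2$centroids, tolerance = 1e-15)

  cfg_short <- cluster_config(clusters = 3, seed = 9, max_iter = 2)
  r3 <- ifrfcm_segment(ph$image, cfg_short)
  expect_false(r3$converged)
  expect_equal(r3$n_iter, 2L)
})
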