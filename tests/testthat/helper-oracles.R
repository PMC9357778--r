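# Independent brute-force oracles: scalar loops and textbook formulas only,
# sharing no code path with the implementations they check.

# geodesic reconstruction by dilation (8-connected), pixel loops to stability
naive_reconstruct_dilation <- function(marker, mask) {
  cur <- pmin(marker, mask)
  nr <- nrow(cur); nc <- ncol(cur)
  repeat {
    nxt <- cur
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      best <- cur[i, j]
      for (di in -1:1) for (dj in -1:1) {
        r <- i + di; cc <- j + dj
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && cur[r, cc] > best) {
          best <- cur[r, cc]
        }
      }
      nxt[i, j] <- min(best, mask[i, j])
    }
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}

naive_erode <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    lo <- Inf
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 > radius^2) next
      r <- i + di; cc <- j + dj
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc && m[r, cc] < lo) lo <- m[r, cc]
    }
    out[i, j] <- lo
  }
  out
}

# opening-by-reconstruction then closing-by-reconstruction, all via loops
naive_open_close_reconstruct <- function(m, radius, K) {
  opened <- naive_reconstruct_dilation(naive_erode(m, radius), m)
  comp <- K - opened
  K - naive_reconstruct_dilation(naive_erode(comp, radius), comp)
}

# pixel-domain FCM (no histogram shortcut): alternating updates from a
# fixed initial centroid vector
naive_pixel_fcm <- function(pixels, init, v = 2, tol = 1e-10, max_iter = 500) {
  x <- as.numeric(pixels)
  cent <- as.numeric(init)
  C <- length(cent)
  e <- 1 / (v - 1)
  for (it in seq_len(max_iter)) {
    D <- outer(cent, x, function(p, z) (z - p)^2)
    U <- matrix(0, C, length(x))
    for (n in seq_along(x)) {
      if (any(D[, n] == 0)) {
        zn <- D[, n] == 0
        U[zn, n] <- 1 / sum(zn)
      } else {
        inv <- D[, n]^(-e)
        U[, n] <- inv / sum(inv)
      }
    }
    Uv <- U^v
    new_cent <- as.vector((Uv %*% x) / rowSums(Uv))
    delta <- max(abs(new_cent - cent))
    cent <- new_cent
    if (delta < tol) break
  }
  cent
}

naive_glcm <- function(m, offset, L, symmetric = TRUE, normalize = TRUE) {
  P <- matrix(0, L, L)
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- i + offset[1]; cc <- j + offset[2]
    if (r >= 1 && r <= nr && cc >= 1 && cc <= nc) {
      P[m[i, j] + 1, m[r, cc] + 1] <- P[m[i, j] + 1, m[r, cc] + 1] + 1
    }
  }
  if (symmetric) P <- P + t(P)
  if (normalize && sum(P) > 0) P <- P / sum(P)
  P
}

naive_haralick <- function(P) {
  L <- nrow(P)
  con <- dis <- ene <- hom <- ent <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    hom <- hom + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log2(p)
    mu_i <- mu_i + (i - 1) * p
    mu_j <- mu_j + (j - 1) * p
  }
  si <- sj <- co <- 0
  for (i in 1:L) for (j in 1:L) {
    si <- si + (i - 1 - mu_i)^2 * P[i, j]
    sj <- sj + (j - 1 - mu_j)^2 * P[i, j]
  }
  si <- sqrt(si); sj <- sqrt(sj)
  if (si > 0 && sj > 0) {
    for (i in 1:L) for (j in 1:L) {
      co <- co + (i - 1 - mu_i) * (j - 1 - mu_j) * P[i, j]
    }
    co <- co / (si * sj)
  }
  c(contrast = con, dissimilarity = dis, energy = ene, homogeneity = hom,
    entropy = ent, correlation = co)
}

# sliding-window adaptive Wiener filter, per-pixel loops
naive_wiener <- function(x, window) {
  half <- (window - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  mu <- va <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -half:half) for (dj in -half:half) {
      r <- i + di; cc <- j + dj
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc) vals <- c(vals, x[r, cc])
    }
    mu[i, j] <- mean(vals)
    va[i, j] <- mean(vals^2) - mean(vals)^2
  }
  noise <- mean(va)
  out <- mu
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (va[i, j] > noise) {
      out[i, j] <- mu[i, j] + (va[i, j] - noise) / va[i, j] * (x[i, j] - mu[i, j])
    }
  }
  out
}

random_gray <- function(nr, nc, levels) {
  gray_image(matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc),
             levels = levels)
}

penrose_ok <- function(Z, Zp, tol = 1e-8) {
  all(abs(Z %*% Zp %*% Z - Z) < tol,
      abs(Zp %*% Z %*% Zp - Zp) < tol,
      abs(t(Z %*% Zp) - Z %*% Zp) < tol,
      abs(t(Zp %*% Z) - Zp %*% Z) < tol)
}

# hand-built one-particle swarm state for injected-randomness step checks
manual_swarm_state <- function(position, velocity, pbest, gbest,
                               pbest_fit = Inf, gbest_fit = Inf) {
  structure(list(positions = matrix(position, 1), velocities = matrix(velocity, 1),
                 pbest = matrix(pbest, 1), pbest_fit = pbest_fit,
                 gbest = gbest, gbest_fit = gbest_fit,
                 iteration = 0L, fitness_history = gbest_fit),
            class = "swarm_state")
}
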