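#' Particle swarm configuration
#'
#' Two update rules are provided. The `inertia` rule is canonical PSO:
#' velocity `w` is damped by an inertia schedule and attracted to the global
#' best (weight `beta`) and the personal best (weight `gamma`), with fresh
#' U(0,1) vectors each step. The `accelerated` rule drops the velocity
#' memory: positions relax toward the global best (`gamma`) plus an
#' annealed random perturbation (`beta`, scaled by the box width times
#' `anneal^n`).
#'
#' @param n_particles swarm size.
#' @param dim search-space dimension.
#' @param lower,upper per-dimension bounds (recycled scalars allowed).
#' @param beta global-best learning parameter (default 2 inertia rule,
#'   0.1 accelerated).
#' @param gamma personal-best (inertia) / relaxation (accelerated)
#'   parameter (default 2 inertia, 0.7 accelerated).
#' @param inertia constant in (0,1) or a function `Phi(n, max_iter)`;
#'   default is the linear decay `0.9 - 0.5 n / max_iter`.
#' @param anneal geometric annealing base of the accelerated noise term.
#' @param max_iter iteration budget.
#' @param seed RNG seed.
#' @param update_rule `"inertia"` or `"accelerated"`.
#' @return list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles, dim, lower = -1, upper = 1,
                         beta = NULL, gamma = NULL, inertia = NULL,
                         anneal = 0.97, max_iter = 100L, seed = NULL,
                         update_rule = c("inertia", "accelerated")) {
  update_rule <- match.arg(update_rule)
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("bounds must satisfy lower < upper")
  if (is.null(beta)) beta <- if (update_rule == "inertia") 2 else 0.1
  if (is.null(gamma)) gamma <- if (update_rule == "inertia") 2 else 0.7
  if (beta < 0 || gamma < 0) stop("beta and gamma must be >= 0")
  if (is.null(inertia)) inertia <- function(n, max_iter) 0.9 - 0.5 * n / max_iter
  if (is.numeric(inertia)) {
    phi <- inertia
    if (phi <= 0 || phi >= 1) stop("constant inertia must lie in (0, 1)")
    inertia <- function(n, max_iter) phi
  }
  structure(list(n_particles = as.integer(n_particles), dim = as.integer(dim),
                 lower = lower, upper = upper, beta = beta, gamma = gamma,
                 inertia = inertia, anneal = anneal,
                 max_iter = as.integer(max_iter), seed = seed,
                 update_rule = update_rule),
            class = "swarm_config")
}

#' Initialise a swarm
#'
#' Positions uniform in the box, velocities uniform in
#' `+/- (upper - lower)/2`; personal and global bests evaluated. Fitness is
#' minimised throughout.
#'
#' @param config a [swarm_config].
#' @param fitness function mapping a position vector to a finite scalar.
#' @return list of class `swarm_state`.
#' @export
init_swarm <- function(config, fitness) {
  n <- config$n_particles; d <- config$dim
  width <- config$upper - config$lower
  pos <- run_seeded(config$seed, {
    p <- matrix(stats::runif(n * d), n, d)
    p <- sweep(sweep(p, 2, width, "*"), 2, config$lower, "+")
    v <- matrix(stats::runif(n * d, -1, 1), n, d)
    v <- sweep(v, 2, width / 2, "*")
    list(p = p, v = v)
  })
  fit <- apply(pos$p, 1, fitness)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1]
    stop(sprintf("non-finite fitness at initial point [%s]",
                 paste(signif(pos$p[bad, ], 4), collapse = ", ")))
  }
  g <- which.min(fit)
  structure(list(positions = pos$p, velocities = pos$v,
                 pbest = pos$p, pbest_fit = fit,
                 gbest = pos$p[g, ], gbest_fit = fit[g],
                 iteration = 0L, fitness_history = fit[g]),
            class = "swarm_state")
}

clamp_positions <- function(pos, vel, lower, upper) {
  for (j in seq_len(ncol(pos))) {
    low <- pos[, j] < lower[j]; high <- pos[, j] > upper[j]
    pos[low, j] <- lower[j]; pos[high, j] <- upper[j]
    vel[low | high, j] <- 0
  }
  list(pos = pos, vel = vel)
}

update_bests <- function(state, fitness) {
  fit <- apply(state$positions, 1, fitness)
  better <- fit < state$pbest_fit
  state$pbest[better, ] <- state$positions[better, , drop = FALSE]
  state$pbest_fit[better] <- fit[better]
  g <- which.min(state$pbest_fit)
  if (state$pbest_fit[g] < state$gbest_fit) {
    state$gbest <- state$pbest[g, ]
    state$gbest_fit <- state$pbest_fit[g]
  }
  state
}

#' One inertia-rule PSO step
#'
#' `w' = Phi(n) w + beta d1 (g* - p) + gamma d2 (p* - p)`, then
#' `p' = p + w'` clamped to the bounds (velocity zeroed on clamped
#' dimensions). `d1`, `d2` are fresh U(0,1) vectors per particle and
#' dimension; `delta_source` injects deterministic values for exact
#' step checking.
#'
#' @param state a [swarm_state].
#' @param config a [swarm_config].
#' @param fitness fitness function.
#' @param delta_source function `(n) -> numeric(n)` supplying the random
#'   vectors (default `runif`).
#' @return updated `swarm_state` (iteration advanced, bests refreshed).
#' @export
step_inertia <- function(state, config, fitness, delta_source = stats::runif) {
  n <- config$n_particles; d <- config$dim
  phi <- config$inertia(state$iteration, config$max_iter)
  d1 <- matrix(delta_source(n * d), n, d)
  d2 <- matrix(delta_source(n * d), n, d)
  gmat <- matrix(state$gbest, n, d, byrow = TRUE)
  vel <- phi * state$velocities +
    config$beta * d1 * (gmat - state$positions) +
    config$gamma * d2 * (state$pbest - state$positions)
  pos <- state$positions + vel
  cl <- clamp_positions(pos, vel, config$lower, config$upper)
  state$positions <- cl$pos; state$velocities <- cl$vel
  state$iteration <- state$iteration + 1L
  state <- update_bests(state, fitness)
  state$fitness_history <- c(state$fitness_history, state$gbest_fit)
  state
}

#' One accelerated-rule PSO step
#'
#' Position update `p' = (1 - gamma) p + gamma g* + beta delta`, with
#' `delta` a fresh U(0,1) vector scaled by the per-dimension box width
#' times `anneal^n` (geometric annealing so the perturbation vanishes).
#'
#' @inheritParams step_inertia
#' @export
step_accelerated <- function(state, config, fitness, delta_source = stats::runif) {
  n <- config$n_particles; d <- config$dim
  width <- config$upper - config$lower
  scale <- matrix(width * config$anneal^state$iteration, n, d, byrow = TRUE)
  delta <- matrix(delta_source(n * d), n, d) * scale
  gmat <- matrix(state$gbest, n, d, byrow = TRUE)
  pos <- (1 - config$gamma) * state$positions + config$gamma * gmat +
    config$beta * delta
  cl <- clamp_positions(pos, state$velocities, config$lower, config$upper)
  state$positions <- cl$pos; state$velocities <- cl$vel
  state$iteration <- state$iteration + 1L
  state <- update_bests(state, fitness)
  state$fitness_history <- c(state$fitness_history, state$gbest_fit)
  state
}

#' Run a particle swarm optimisation
#'
#' Minimises `fitness` over the box for `max_iter` steps of the configured
#' update rule. Fully deterministic given `config$seed`; ties (e.g. a
#' constant landscape) keep the first evaluated best.
#'
#' @param config a [swarm_config].
#' @param fitness function to minimise.
#' @return list `best` (position), `best_fitness`, `history`
#'   (global-best fitness per iteration, length `max_iter + 1`), `state`.
#' @export
pso_optimize <- function(config, fitness) {
  step <- if (config$update_rule == "inertia") step_inertia else step_accelerated
  # init_swarm seeds itself from config$seed; the step stream uses a derived
  # seed so the two do not overlap
  step_seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  run_seeded(step_seed, {
    state <- init_swarm(config, fitness)
    for (it in seq_len(config$max_iter)) {
      state <- step(state, config, fitness)
    }
    list(best = state$gbest, best_fitness = state$gbest_fit,
         history = state$fitness_history, state = state)
  })
}

#' Train an ELM with PSO-optimised input weights
#'
#' Each particle encodes the flattened H x J input-weight matrix followed by
#' the H biases (dimension `H*J + H`, bounds `[-1, 1]`). A particle's
#' fitness is the misclassification rate of the ELM it induces — output
#' weights solved on the training set by pseudoinverse — evaluated on the
#' validation set; ties are broken toward lower validation MSE via a
#' bounded smooth penalty (`1e-3 * mse/(1+mse)`, always smaller than one
#' misclassified sample). Features are standardised with training-set
#' statistics.
#'
#' @param X_train,y_train training features (N x J) and 0-based labels.
#' @param X_val,y_val validation features and labels.
#' @param H hidden-unit count.
#' @param n_particles,max_iter,seed swarm settings.
#' @param activation ELM activation name.
#' @param update_rule PSO update rule.
#' @return list `model` (trained [elm_model] rebuilt from the best
#'   particle), `history` (validation fitness per iteration),
#'   `val_accuracy`.
#' @export
pso_elm_train <- function(X_train, y_train, X_val, y_val, H = 10L,
                          n_particles = 20L, max_iter = 50L, seed = NULL,
                          activation = "sigmoid",
                          update_rule = "inertia") {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (nrow(X_val) == 0) stop("empty validation set")
  J <- ncol(X_train)
  O <- max(c(y_train, y_val)) + 1L
  d_train <- one_hot(y_train, O)
  d_val <- one_hot(y_val, O)
  proto <- init_elm(J, H, O, activation, seed = 0L)
  proto <- elm_set_scaling(proto, X_train)

  build <- function(particle) {
    m <- proto
    m$W <- matrix(particle[seq_len(H * J)], H, J)
    m$k <- particle[H * J + seq_len(H)]
    m
  }
  fitness <- function(particle) {
    m <- train_elm(build(particle), X_train, d_train)
    pred <- predict(m, X_val)
    err <- mean(pred$class != y_val)
    mse <- mean((pred$Y - d_val)^2)
    err + 1e-3 * mse / (1 + mse)
  }
  cfg <- swarm_config(n_particles = n_particles, dim = H * J + H,
                      lower = -1, upper = 1, max_iter = max_iter,
                      seed = seed, update_rule = update_rule)
  res <- pso_optimize(cfg, fitness)
  model <- train_elm(build(res$best), X_train, d_train)
  acc <- mean(predict(model, X_val)$class == y_val)
  list(model = model, history = res$history, best_fitness = res$best_fitness,
       val_accuracy = acc)
}
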