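sphere <- function(x) sum(x^2)

test_that("swarm initialisation is seeded, bounded and evaluates bests", {
  cfg <- swarm_config(10, 3, lower = -2, upper = 2, max_iter = 5, seed = 11)
  s1 <- init_swarm(cfg, sphere)
  s2 <- init_swarm(cfg, sphere)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$positions >= -2 & s1$positions <= 2))
  expect_equal(s1$gbest_fit, min(apply(s1$positions, 1, sphere)))
  expect_error(init_swarm(cfg, function(x) NaN), "non-finite fitness")
})

test_that("inertia step reproduces hand arithmetic with injected randomness", {
  cfg <- swarm_config(1, 1, lower = -10, upper = 10, beta = 2, gamma = 2,
                      inertia = 0.9, max_iter = 10, update_rule = "inertia")
  st <- manual_swarm_state(position = 1, velocity = 0.1, pbest = 0.5, gbest = 0)
  out <- step_inertia(st, cfg, sphere, delta_source = function(n) rep(0.5, n))
  expect_equal(out$velocities[1, 1], -1.41, tolerance = 1e-12)
  expect_equal(out$positions[1, 1], -0.41, tolerance = 1e-12)

  # particle sitting at both bests: velocity scales by Phi exactly
  st2 <- manual_swarm_state(position = 2, velocity = 0.4, pbest = 2, gbest = 2)
  out2 <- step_inertia(st2, cfg, sphere, delta_source = function(n) rep(0.123, n))
  expect_equal(out2$velocities[1, 1], 0.9 * 0.4, tolerance = 1e-12)

  # beta = gamma = 0, Phi = 0.5: velocity halves each step
  cfg0 <- swarm_config(1, 1, lower = -10, upper = 10, beta = 0, gamma = 0,
                       inertia = 0.5, max_iter = 10)
  st3 <- manual_swarm_state(position = 0, velocity = 1, pbest = 0, gbest = 0)
  st3 <- step_inertia(st3, cfg0, sphere)
  st3 <- step_inertia(st3, cfg0, sphere)
  expect_equal(st3$velocities[1, 1], 0.25, tolerance = 1e-12)
})

test_that("accelerated step reproduces hand arithmetic and its limit cases", {
  # bounds of unit width at iteration 0 make the annealing scale exactly 1
  cfg <- swarm_config(1, 1, lower = 1.03, upper = 2.03, beta = 0.1, gamma = 0.5,
                      max_iter = 10, update_rule = "accelerated")
  st <- manual_swarm_state(position = 2, velocity = 0, pbest = 2, gbest = 0)
  out <- step_accelerated(st, cfg, sphere, delta_source = function(n) rep(0.3, n))
  expect_equal(out$positions[1, 1], 1.03, tolerance = 1e-12)

  # gamma = 1, beta = 0: jump to the global best
  cfgj <- swarm_config(1, 1, lower = -5, upper = 5, beta = 0, gamma = 1,
                       max_iter = 10, update_rule = "accelerated")
  stj <- manual_swarm_state(position = 3, velocity = 0, pbest = 3, gbest = -1)
  expect_equal(step_accelerated(stj, cfgj, sphere)$positions[1, 1], -1)

  # gamma = beta = 0: position unchanged
  cfg0 <- swarm_config(1, 1, lower = -5, upper = 5, beta = 0, gamma = 0,
                       max_iter = 10, update_rule = "accelerated")
  expect_equal(step_accelerated(stj, cfg0, sphere)$positions[1, 1], 3)
})

test_that("optimizer is deterministic, bounded, monotone and handles flat landscapes", {
  cfg <- swarm_config(15, 2, lower = 0, upper = 1, max_iter = 30, seed = 8)
  r1 <- pso_optimize(cfg, sphere)
  r2 <- pso_optimize(cfg, sphere)
  expect_identical(r1$best, r2$best)
  expect_true(all(r1$best >= 0 & r1$best <= 1))
  expect_true(all(diff(r1$history) <= 0))
  expect_length(r1$history, 31L)

  flat <- pso_optimize(cfg, function(x) 42)
  expect_equal(flat$best_fitness, 42)
  expect_true(all(flat$history == 42))
})

test_that("PSO-ELM beats chance on separable Gaussians and keeps its bookkeeping", {
  set.seed(7)
  n <- 40
  X <- rbind(matrix(rnorm(n, -3, 0.5), n / 2, 2),
             matrix(rnorm(n, 3, 0.5), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  ord <- sample(n)
  X <- X[ord, ]; y <- y[ord]
  fit <- pso_elm_train(X[1:20, ], y[1:20], X[21:40, ], y[21:40],
                       H = 10, n_particles = 20, max_iter = 50, seed = 7)
  expect_gte(fit$val_accuracy, 0.95)
  expect_equal(fit$best_fitness, min(fit$history), tolerance = 1e-15)
  expect_true(all(diff(fit$history) <= 0))

  fit2 <- pso_elm_train(X[1:20, ], y[1:20], X[21:40, ], y[21:40],
                        H = 10, n_particles = 20, max_iter = 50, seed = 7)
  expect_identical(fit$model$W, fit2$model$W)
  expect_error(pso_elm_train(X[1:20, ], y[1:20], X[0, , drop = FALSE],
                             integer(0), H = 5), "empty validation")
})
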