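test_that("corner doves are anchored to the box corners exactly", {
  cfg <- swarm_config(4, 5, dim = 4, lower = 0, upper = 1)
  st <- swarm_initialize(cfg)
  g <- st$grid
  expect_equal(st$positions[g[, 1] == 1 & g[, 2] == 1, ], rep(0, 4))
  expect_equal(st$positions[g[, 1] == 4 & g[, 2] == 5, ], rep(1, 4))
  expect_equal(st$positions[g[, 1] == 1 & g[, 2] == 5, ], c(0, 0, 1, 1))
  expect_equal(st$positions[g[, 1] == 4 & g[, 2] == 1, ], c(1, 1, 0, 0))
  # odd dimension splits at floor(M/2)
  st5 <- swarm_initialize(swarm_config(3, 3, dim = 5))
  g5 <- st5$grid
  expect_equal(st5$positions[g5[, 1] == 1 & g5[, 2] == 3, ], c(0, 0, 1, 1, 1))
  # corners stay anchored under random dispersion too
  str <- swarm_initialize(swarm_config(3, 3, dim = 4, init = "random", seed = 2))
  expect_equal(str$positions[1, ], rep(0, 4))
  expect_error(swarm_config(1, 5), "2x2")
  expect_error(swarm_config(3, 3, dim = 2, lower = 1, upper = 1), "lower < upper")
})

test_that("interior doves interpolate the corners bilinearly", {
  st <- swarm_initialize(swarm_config(3, 3, dim = 2))
  center <- st$positions[st$grid[, 1] == 2 & st$grid[, 2] == 2, ]
  expect_equal(center, c(0.5, 0.5))
})

test_that("the learning rate decays linearly from 0.1 to 0", {
  cfg <- swarm_config(5, 5, dim = 2, max_epochs = 100)
  expect_identical(dove_learning_rate(0, cfg), 0.1)
  expect_identical(dove_learning_rate(100, cfg), 0)
  expect_equal(dove_learning_rate(50, cfg), 0.05)
})

test_that("satisfaction updates follow the decayed exponential-gap recursion", {
  cfg <- swarm_config(2, 2, dim = 2, satisfaction_decay = 0.9)
  st <- swarm_initialize(cfg)
  st <- swarm_update_satisfaction(st, rep(3.3, 4), cfg)
  expect_equal(st$satisfaction, rep(1, 4))
  expect_identical(st$best_satisfaction_idx, 1L)
  expect_identical(st$best_fitness_idx, 1L)
  # two epochs with constant gaps, decay 0.5: S = 0.5*g + g
  cfg2 <- swarm_config(2, 2, dim = 2, satisfaction_decay = 0.5)
  st2 <- swarm_initialize(cfg2)
  fit <- c(0, -1, -2, -0.5)
  g <- exp(fit - max(fit))
  st2 <- swarm_update_satisfaction(st2, fit, cfg2)
  st2 <- swarm_update_satisfaction(st2, fit, cfg2)
  expect_equal(st2$satisfaction, 0.5 * g + g, tolerance = 1e-12)
  # the best dove always receives the maximal increment exp(0) = 1
  expect_equal(max(g), g[1])
  expect_error(swarm_update_satisfaction(st2, c(0, NA, 1, 2), cfg2), "fitness")
})

test_that("move kinematics: best dove and maximally distant doves are stationary", {
  cfg <- swarm_config(2, 2, dim = 1, lower = 0, upper = 1)
  st <- swarm_initialize(cfg)
  st$positions <- matrix(c(0, 1, 0.5, 0.25), 4, 1)
  st <- swarm_update_satisfaction(st, c(5, 1, 2, 3), cfg)
  before <- st$positions
  st <- swarm_move(st, cfg)
  expect_equal(st$positions[1, ], before[1, ])      # most satisfied
  expect_equal(st$positions[2, ], before[2, ])      # at maxDistance
  expect_lt(abs(st$positions[4, ] - 0.25) ,
            abs(before[4, ] - before[1, ]))          # others move toward d_s
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_identical(st$epoch, 1L)
})

test_that("the two-dove line example produces no motion", {
  cfg <- swarm_config(2, 2, dim = 1)
  st <- swarm_initialize(cfg)
  st$positions <- matrix(c(0, 1, 0, 1), 4, 1)
  st$satisfaction <- c(2, 1, 2, 1)
  st$best_satisfaction_idx <- 1L
  st$fitness <- c(2, 1, 2, 1)
  before <- st$positions
  st <- swarm_move(st, cfg)
  # doves at positions 0 coincide with d_s (beta first factor or distance 0);
  # doves at 1 sit at maxDistance, so beta = 0 throughout
  expect_equal(st$positions, before)
})

test_that("optimization locates a sphere optimum and accounts every evaluation", {
  counter <- new.env(); counter$n <- 0L
  obj <- function(w) { counter$n <- counter$n + 1L; -sum((w - 0.3)^2) }
  hits <- 0L
  for (s in 1:20) {
    counter$n <- 0L
    cfg <- swarm_config(5, 5, dim = 2, max_epochs = 100, seed = s)
    res <- dso_optimize(obj, cfg)
    expect_identical(counter$n, 25L * res$epochs_used)
    if (res$best_fitness >= -1e-2) hits <- hits + 1L
    expect_true(all(diff(cummax(res$history)) >= 0))
    expect_true(all(res$state$positions >= 0 & res$state$positions <= 1))
  }
  expect_gte(hits, 18L)
})

test_that("a zero-epoch budget returns the best of initialization with N evaluations", {
  counter <- new.env(); counter$n <- 0L
  obj <- function(w) { counter$n <- counter$n + 1L; -sum(w^2) }
  res <- dso_optimize(obj, swarm_config(5, 5, dim = 2, max_epochs = 0))
  expect_identical(counter$n, 25L)
  expect_identical(res$epochs_used, 1L)
  expect_equal(res$best_position, c(0, 0))
})

test_that("a constant objective leaves the best-fitness history flat", {
  res <- dso_optimize(function(w) 1.5,
                      swarm_config(3, 3, dim = 2, max_epochs = 20))
  expect_true(all(res$history == 1.5))
})

test_that("identical config and seed reproduce the whole trajectory", {
  obj <- function(w) -sum((w - 0.6)^2)
  cfg <- swarm_config(4, 4, dim = 3, max_epochs = 30, init = "random", seed = 77)
  r1 <- dso_optimize(obj, cfg)
  r2 <- dso_optimize(obj, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("a configured target value stops the search early", {
  obj <- function(w) -sum((w - 0.5)^2)
  cfg <- swarm_config(5, 5, dim = 2, max_epochs = 100, target_value = 0,
                      epsilon = 0.05)
  res <- dso_optimize(obj, cfg)
  expect_lt(res$epochs_used, 100)
})

test_that("wrapper selection keeps the informative columns it is given", {
  ft <- make_feature_table(150, 10, 3, seed = 5, gap = 2.5)
  sel <- dso_select_features(ft$x, ft$labels,
                             config = swarm_config(4, 4, dim = 10,
                                                   max_epochs = 15,
                                                   init = "random", seed = 5),
                             seed = 5)
  expect_true(length(sel$selected) >= 1)
  expect_gte(sum(ft$informative %in% sel$selected), 2)
  expect_gt(sel$cv_score, 0.6)
  expect_error(dso_select_features(ft$x[, 1, drop = FALSE], ft$labels), "2 features")
  expect_error(dso_select_features(ft$x, rep(0, 150)), "single-class")
})
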