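sphere2 <- benchmark_function("F1", dimension = 2)

test_that("transfer factor follows exp((t - t_max)/t_max)", {
  expect_equal(transfer_factor(500, 500), 1.0)
  expect_equal(transfer_factor(0, 500), exp(-1))
  expect_equal(transfer_factor(250, 500), exp(-0.5))
  ts <- seq(1, 500)
  expect_true(all(diff(transfer_factor(ts, 500)) > 0))
  expect_error(transfer_factor(1, 0), "positive")
})

test_that("density factor decays from e to zero", {
  expect_equal(density_factor(500, 500), 0.0)
  expect_equal(density_factor(0, 500), exp(1))
  ts <- seq(0, 500)
  expect_true(all(diff(density_factor(ts, 500)) < 0))
  expect_error(density_factor(1, 0), "positive")
})

test_that("initialization is seeded, in bounds, with the fittest incumbent", {
  set.seed(5)
  p1 <- initialize_population(sphere2$fn, c(0, 0), c(1, 1), 12)
  set.seed(5)
  p2 <- initialize_population(sphere2$fn, c(0, 0), c(1, 1), 12)
  expect_identical(p1, p2)
  expect_true(all(p1$X >= 0 & p1$X <= 1))
  expect_true(all(p1$den > 0 & p1$den < 1))
  expect_equal(p1$best$fit, min(p1$fit))
  expect_error(
    initialize_population(function(x) NaN, c(0, 0), c(1, 1), 4),
    "not finite")
})

test_that("density/volume drift toward the incumbent with fixed points", {
  set.seed(1)
  pop <- initialize_population(sphere2$fn, c(-1, -1), c(1, 1), 6)
  pop$den <- rep(pop$best$den, 6)   # at the fixed point
  upd <- update_density_volume(pop)
  expect_equal(upd$den, pop$den)
  # strictly between old value and target otherwise
  pop$den <- rep(0.2, 6)
  pop$best$den <- 0.8
  upd <- update_density_volume(pop)
  expect_true(all(upd$den >= 0.2 & upd$den <= 0.8))
})

test_that("acceleration update arithmetic matches the stated forms", {
  set.seed(2)
  pop <- initialize_population(sphere2$fn, c(-1, -1), c(1, 1), 5)
  pop$den <- rep(1, 5)
  pop$vol <- rep(1, 5)
  pop$best$den <- 0.5
  pop$best$vol <- 0.5
  pop$best$acc <- c(1, 1)
  # exploitation branch (TF > 0.5), plain arithmetic: (0.5 + 0.5*1)/(1*1)
  upd <- update_acceleration(pop, TF = 0.9, dispersion = FALSE)
  expect_equal(unname(upd$acc), matrix(1, 5, 2))
  # exploration with all materials identical -> identical accelerations
  pop$acc <- matrix(2, 5, 2)
  upd <- update_acceleration(pop, TF = 0.4, dispersion = FALSE)
  expect_equal(unname(upd$acc), matrix(3, 5, 2))
  # TF exactly 0.5 takes the exploration branch (random-material numerator)
  upd <- update_acceleration(pop, TF = 0.5, dispersion = FALSE)
  expect_equal(unname(upd$acc), matrix(3, 5, 2))
})

test_that("acceleration normalization maps onto [l, u + l]", {
  set.seed(3)
  pop <- initialize_population(sphere2$fn, c(-1, -1), c(1, 1), 3)
  pop$acc <- matrix(c(0, 0, 0.5, 0.5, 1, 1), 3, 2, byrow = TRUE)
  out <- normalize_acceleration(pop, u = 0.9, l = 0.1)
  expect_equal(out$acc_norm[1, ], c(0.1, 0.1))
  expect_equal(out$acc_norm[2, ], c(0.55, 0.55))
  expect_equal(out$acc_norm[3, ], c(1.0, 1.0))
  expect_identical(out$acc, out$acc_norm)   # carried to the next iteration
  pop$acc <- matrix(4, 3, 2)
  out <- normalize_acceleration(pop, u = 0.9, l = 0.1)
  expect_equal(unname(out$acc_norm), matrix(0.1, 3, 2))
})

test_that("position update honours its zero-step fixed points", {
  cfg <- aoa_config(pop = 4, iters = 10, seed = 1)
  set.seed(4)
  pop <- initialize_population(sphere2$fn, c(-5, -5), c(5, 5), 4)
  pop <- normalize_acceleration(pop)
  # zero density factor freezes the exploration step
  frozen <- update_positions(pop, TF = 0.4, dfac = 0, cfg, sphere2$fn)
  expect_equal(frozen$X, pop$X)
  # exploitation with x_i = T * x_best collapses onto the incumbent
  TF <- 0.9
  Tt <- cfg$C3 * TF
  pop2 <- pop
  pop2$X <- matrix(Tt * pop$best$x, 4, 2, byrow = TRUE)
  moved <- update_positions(pop2, TF = TF, dfac = 1.0, cfg, sphere2$fn)
  expect_equal(unname(moved$X),
               matrix(pop$best$x, 4, 2, byrow = TRUE))
})

test_that("optimization is seeded, monotone and converges on the sphere", {
  res <- aoa_optimize(sphere2, config = aoa_config(pop = 30, iters = 500,
                                                   seed = 42))
  expect_lt(res$best_value, 1e-6)
  expect_true(all(diff(res$trace) <= 0))
  res2 <- aoa_optimize(sphere2, config = aoa_config(pop = 30, iters = 500,
                                                    seed = 42))
  expect_identical(res$trace, res2$trace)
  # zero iterations return the best of the initial population
  res0 <- aoa_optimize(sphere2, config = aoa_config(pop = 10, iters = 0,
                                                    seed = 1))
  expect_length(res0$trace, 1)
  expect_equal(res0$best_value, res0$trace[1])
})

test_that("late iterations are exploitation-dominated", {
  tf <- transfer_factor(seq_len(500), 500)
  expect_gt(mean(tf > 0.5), 0.5)
})

test_that("positions stay within bounds along a whole run", {
  f <- benchmark_function("F6", dimension = 3)
  cfg <- aoa_config(pop = 8, iters = 60, seed = 9)
  set.seed(cfg$seed)
  pop <- initialize_population(f$fn, f$lower, f$upper, cfg$pop)
  for (t in seq_len(cfg$iters)) {
    pop <- iaoadbn:::aoa_iterate(pop, t, cfg, f$fn)
    expect_true(all(pop$X >= matrix(f$lower, 8, 3, byrow = TRUE) &
                      pop$X <= matrix(f$upper, 8, 3, byrow = TRUE)))
  }
})
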