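test_that("adaptive multiplier endpoints and closed form", {
  expect_identical(adaptive_M(0, 100), 1)
  expect_identical(adaptive_M(100, 100), 0)
  expect_identical(adaptive_M(50, 100), 0.5)
  set.seed(20)
  for (i in 1:100) {
    Qmax <- sample(10:500, 1)
    Q <- sample(0:Qmax, 1)
    expect_equal(adaptive_M(Q, Qmax), (1 - Q / Qmax)^(2 * Q / Qmax))
  }
  expect_error(adaptive_M(-1, 10), "out of range")
  expect_error(adaptive_M(11, 10), "out of range")
})

test_that("Brownian steps have standard-normal moments", {
  set.seed(21)
  v <- brownian_vector(1e5)
  expect_lt(abs(mean(v)), 3 / sqrt(1e5))
  expect_lt(abs(var(v) - 1), 3 * sqrt(2 / 1e5))
})

test_that("Levy steps are heavy-tailed with the configured exponent", {
  set.seed(22)
  v <- abs(levy_vector(1e5, 1.5))
  q <- quantile(v, probs = seq(0.9, 0.999, by = 0.004), names = FALSE)
  surv <- vapply(q, function(t) mean(v > t), numeric(1))
  slope <- coef(lm(log(surv) ~ log(q)))[2]
  expect_lt(abs(slope - (-1.5)), 0.2)
  set.seed(5); a <- levy_vector(10)
  set.seed(5); b <- levy_vector(10)
  expect_identical(a, b)
})

test_that("initial population is uniform inside the box", {
  cfg <- pcso_config(dim = 3, lower = c(-1, 0, 2), upper = c(1, 4, 2.5),
                     pop_size = 10000L, max_iters = 3L, seed = 1)
  set.seed(cfg$seed)
  sw <- init_population(cfg, function(x) sum(x^2))
  expect_true(all(t(sw$prey) >= cfg$lower & t(sw$prey) <= cfg$upper))
  mid <- (cfg$lower + cfg$upper) / 2
  se <- (cfg$upper - cfg$lower) / sqrt(12 * cfg$pop_size)
  expect_true(all(abs(colMeans(sw$prey) - mid) <= 3 * se + 1e-12))
  # degenerate zero-width box pins every agent
  cfg0 <- pcso_config(dim = 2, lower = c(1, 2), upper = c(1, 2),
                      pop_size = 5L, max_iters = 3L)
  sw0 <- init_population(cfg0, function(x) sum(x))
  expect_true(all(sw0$prey[, 1] == 1 & sw0$prey[, 2] == 2))
})

test_that("phase steps are fixed points when the step constant vanishes", {
  cfg <- pcso_config(dim = 4, lower = -2, upper = 2, pop_size = 6L,
                     max_iters = 9L, step_constant = 0, seed = 2)
  set.seed(2)
  sw <- init_population(cfg, function(x) sum(x^2))
  for (f in list(phase1_step, phase2_step, phase3_step)) {
    out <- f(sw, 1, cfg)
    expect_equal(out$prey, sw$prey, tolerance = 1e-14)
  }
})

test_that("phase-2 splits the population in half and phase-3 freezes at M=0", {
  cfg <- pcso_config(dim = 2, lower = -1, upper = 1, pop_size = 4L,
                     max_iters = 9L, seed = 3)
  set.seed(3)
  sw <- init_population(cfg, function(x) sum(x^2))
  # at Q = Qmax, adaptive_M = 0 so branch-2 / phase-3 agents cannot move
  out3 <- phase3_step(sw, cfg$max_iters, cfg)
  expect_equal(out3$prey, sw$prey, tolerance = 1e-14)
  out2 <- phase2_step(sw, cfg$max_iters, cfg)
  expect_equal(out2$prey[3:4, ], sw$prey[3:4, ], tolerance = 1e-14)
  expect_false(isTRUE(all.equal(out2$prey[1:2, ], sw$prey[1:2, ])))
})

test_that("raid jump masks the expected fraction of coordinates", {
  cfg <- pcso_config(dim = 10000L, lower = -1, upper = 1, pop_size = 4L,
                     max_iters = 10L, mask_prob = 0.2, seed = 4)
  x <- numeric(10000L)
  set.seed(4)
  out <- raid_jump(x, cfg, Q = 1)
  frac <- mean(out != 0)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # mask probability zero leaves the position unchanged
  cfg0 <- pcso_config(dim = 5, lower = -1, upper = 1, pop_size = 4L,
                      max_iters = 10L, mask_prob = 0)
  expect_identical(raid_jump(rep(0.3, 5), cfg0, 1), rep(0.3, 5))
  # at Q = Qmax the multiplier is zero regardless of the mask
  cfg1 <- pcso_config(dim = 5, lower = -1, upper = 1, pop_size = 4L,
                      max_iters = 10L, mask_prob = 1)
  expect_identical(raid_jump(rep(0.3, 5), cfg1, 10), rep(0.3, 5))
})

test_that("crow step moves along the segment toward the followed memory", {
  x <- c(0, 0); memj <- c(2, 4)
  expect_identical(crow_step(x, x, 2.0), x)
  set.seed(6)
  for (i in 1:20) {
    out <- crow_step(x, memj, flight_length = 1)
    lambda <- out / memj
    expect_equal(lambda[1], lambda[2], tolerance = 1e-12)
    expect_gte(lambda[1], 0)
    expect_lte(lambda[1], 1)
  }
})

test_that("hybrid update is the clipped midpoint", {
  expect_identical(hybrid_update(c(1, 1), c(1, 1)), c(1, 1))
  expect_identical(hybrid_update(c(0, 0), c(2, 2)), c(1, 1))
  r <- runif(5); s <- runif(5)
  h <- hybrid_update(r, s)
  expect_true(all(h >= pmin(r, s) & h <= pmax(r, s)))
  expect_identical(hybrid_update(c(0, 0), c(10, 10), lower = c(-1, -1),
                                 upper = c(2, 2)), c(2, 2))
  expect_error(hybrid_update(1:2, 1:3), "mismatch")
})

test_that("optimization is monotone, bounded, seeded and phase-dispatched", {
  cfg <- pcso_config(dim = 3, lower = -4, upper = 4, pop_size = 8L,
                     max_iters = 30L, seed = 7)
  seen <- new.env(); seen$ok <- TRUE
  obj <- function(x) {
    if (any(x < -4 - 1e-12) || any(x > 4 + 1e-12)) seen$ok <- FALSE
    sum(x^2)
  }
  r1 <- pcso_optimize(obj, cfg)
  expect_true(seen$ok)
  expect_true(all(diff(r1$history) <= 0))
  expect_equal(r1$evaluations, cfg$pop_size * (2L * cfg$max_iters + 1L))
  r2 <- pcso_optimize(function(x) sum(x^2), cfg)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$history, r2$history)
  # phase dispatch at the iteration thirds
  expect_identical(vapply(1:9, pcso_phase, integer(1), Qmax = 9),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L))
  # constant objective: flat history at the constant
  rc <- pcso_optimize(function(x) 42, cfg)
  expect_true(all(rc$history == 42))
})

test_that("non-finite objective values abort with a diagnostic", {
  cfg <- pcso_config(dim = 2, lower = -1, upper = 1, pop_size = 4L,
                     max_iters = 5L, seed = 8)
  expect_error(pcso_optimize(function(x) NaN, cfg), "non-finite")
})

test_that("early stopping on stagnation truncates the run when enabled", {
  cfg <- pcso_config(dim = 2, lower = -1, upper = 1, pop_size = 6L,
                     max_iters = 50L, seed = 9, stagnation_window = 5L)
  r <- pcso_optimize(function(x) 1, cfg)
  expect_lt(length(r$history), 50L)
})
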