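test_that("action grid has 121 actions with the stated levels", {
  g <- action_grid()
  expect_equal(nrow(g), 121)
  lv <- action_levels()
  expect_equal(lv[c(1, 6, 11)], c(-2, 0, 2))
  # index decomposition: x level fastest
  expect_equal(unname(action_accel(0L)), matrix(c(-2, -2), 1))
  expect_equal(unname(action_accel(120L)), matrix(c(2, 2), 1))
  expect_equal(unname(action_accel(60L)), matrix(c(0, 0), 1))  # centre
  expect_error(action_accel(121L), "action_index")
  expect_error(action_accel(-1L), "action_index")
})

test_that("field force is symmetric, empty-sum zero, and decays", {
  cfg <- env_config(attractors = list(),
                    repellers = list(list(pos = c(0.3, 0.5), strength = 1),
                                     list(pos = c(0.7, 0.5), strength = 1)),
                    sigma_f = 0.2)
  f <- field_force(c(0.5, 0.5), cfg)
  expect_equal(f[1], 0)  # equidistant between equal repellers
  empty <- env_config(attractors = list(), repellers = list())
  expect_equal(field_force(c(0.3, 0.9), empty), c(0, 0))
  # far from all sources the Gaussian profile is analytically negligible:
  # |F| = k (r / sigma) exp(-r^2 / (2 sigma^2))
  cfg2 <- env_config()
  r <- 10
  k_tot <- sum(cfg2$attractors$strength) + sum(cfg2$repellers$strength)
  bound <- k_tot * (r / cfg2$sigma_f) * exp(-r^2 / (2 * cfg2$sigma_f^2))
  expect_lt(bound, 1e-6)
  expect_lt(sqrt(sum(field_force(c(10, 10), cfg2)^2)), 1e-6)
  expect_error(field_force(c(NaN, 0), cfg2), "corrupted")
})

test_that("a resting state with zero action and no sources is a fixed point", {
  cfg <- env_config(attractors = list(), repellers = list())
  s <- c(0.5, 0.5, 0, 0)
  expect_equal(env_step(s, 60L, cfg), s)
})

test_that("free motion advances position by v * dt", {
  cfg <- env_config(attractors = list(), repellers = list())
  s <- c(0.5, 0.5, 0.4, 0)
  s2 <- env_step(s, 60L, cfg)
  expect_equal(s2[1], 0.5 + 0.4 * cfg$dt)
  expect_equal(s2[3], 0.4)
})

test_that("boundary contact zeroes only the violating axis (sliding)", {
  cfg <- env_config(attractors = list(), repellers = list())
  s <- c(1, 0.5, 0.5, 0.3)
  s2 <- env_step(s, 120L, cfg)  # accelerate (+2, +2) into the x wall
  expect_equal(s2[1], 1)
  expect_equal(s2[3], 0)
  expect_gt(s2[2], 0.5)  # y keeps moving
  expect_gt(s2[4], 0.3)
  cfg_stop <- env_config(attractors = list(), repellers = list(),
                         boundary = "stop")
  s3 <- env_step(s, 120L, cfg_stop)
  expect_equal(s3[3:4], c(0, 0))
})

test_that("rollouts are deterministic and stay inside the unit square", {
  cfg <- env_config()
  r1 <- env_rollout(cfg, 400, seed = 11)
  r2 <- env_rollout(cfg, 400, seed = 11)
  expect_identical(r1$states, r2$states)
  expect_true(all(r1$states[, 1:2] >= 0 & r1$states[, 1:2] <= 1))
  # replaying the recorded actions reproduces the trajectory bitwise
  s <- env_reset(cfg)
  for (t in seq_along(r1$actions)) s <- env_step(s, r1$actions[t], cfg)
  expect_identical(s, r1$states[nrow(r1$states), ])
})

test_that("a constant action yields monotone displacement without sources", {
  cfg <- env_config(attractors = list(), repellers = list())
  s <- env_reset(cfg)
  xs <- s[1]
  for (i in 1:60) {
    s <- env_step(s, 62L, cfg)  # acceleration (+0.8, 0)
    xs <- c(xs, s[1])
  }
  hit <- which(xs == 1)[1]
  upto <- if (is.na(hit)) length(xs) else hit
  expect_true(all(diff(xs[1:upto]) > 0))
})

test_that("uniform random rollouts are biased toward the attractor", {
  cfg <- env_config()
  att <- cfg$attractors$pos[1, ]
  for (seed in 1:3) {
    ro <- env_rollout(cfg, 1500, seed = seed)
    P <- ro$states[, 1:2]
    near_att <- mean(sqrt(rowSums(sweep(P, 2, att)^2)) < 0.3)
    for (i in seq_along(cfg$repellers$strength)) {
      rep_i <- cfg$repellers$pos[i, ]
      near_rep <- mean(sqrt(rowSums(sweep(P, 2, rep_i)^2)) < 0.3)
      expect_gt(near_att, near_rep)
    }
  }
})

test_that("reset is deterministic with zero velocities and unit CR cell", {
  cfg <- env_config()
  s <- env_reset(cfg)
  expect_identical(s, env_reset(cfg))
  expect_equal(s[1:2], cfg$initial_position)
  expect_equal(s[3:4], c(0, 0))
  expect_equal(coverage_rate(matrix(s[1:2], 1)), 1 / 2500)
})

test_that("batched stepping matches the scalar step", {
  cfg <- env_config()
  set.seed(5)
  S <- cbind(runif(20), runif(20), rnorm(20), rnorm(20))
  a <- sample(0:120, 20, replace = TRUE)
  batch <- env_step_accel(S, action_accel(a), cfg)
  for (i in c(1, 7, 20))
    expect_equal(batch[i, ], env_step(S[i, ], a[i], cfg))
})

test_that("environment config round-trips through YAML", {
  cfg <- env_config(sigma_f = 0.27, initial_position = c(0.2, 0.4))
  path <- tempfile(fileext = ".yaml")
  write_env_config(cfg, path)
  cfg2 <- read_env_config(path)
  expect_equal(cfg2$sigma_f, 0.27)
  expect_equal(cfg2$attractors, cfg$attractors)
  expect_equal(cfg2$initial_position, c(0.2, 0.4))
})
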