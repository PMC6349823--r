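test_that("policy distribution is a proper softmax over 121 actions", {
  pp <- tiny_pp()
  set.seed(1)
  S <- rand_state(5)
  P <- policy_distribution(pp, S)
  expect_equal(dim(P), c(5, 121))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-8)
  # zero logits give the uniform distribution
  pp0 <- pp
  pp0$net <- zero_net(pp0$net)
  expect_equal(policy_distribution(pp0, S[1, ]), rep(1 / 121, 121))
  # softmax shift invariance: adding a constant to every logit bias
  pp2 <- pp
  pp2$net$par$b_logits <- pp2$net$par$b_logits + 3.7
  expect_equal(policy_distribution(pp2, S), P, tolerance = 1e-12)
})

test_that("value loss realises the fitted-policy-evaluation contract", {
  vp <- tiny_vp()
  set.seed(2)
  S <- rand_state(6)
  S2 <- rand_state(6)
  # gamma = 0 with v forced to match R exactly gives zero loss
  vp0 <- vp
  vp0$net <- zero_net(vp0$net)
  vp0$net$par$b_v <- 0.7
  vp0$target_par <- vp0$net$par
  expect_equal(value_loss(vp0, S, rep(0.7, 6), S2, gamma = 0), 0)
  # constant v with zero rewards is self-consistent at gamma = 1
  expect_equal(value_loss(vp0, S, rep(0, 6), S2, gamma = 1),
               mean((0 + 1 * 0.7 - 0.7)^2))
  # recomputation oracle on random networks
  R <- rnorm(6)
  y <- R + 0.9 * state_value(vp, S2, target = TRUE)
  expect_equal(value_loss(vp, S, R, S2, gamma = 0.9),
               mean((y - state_value(vp, S))^2))
})

test_that("the value target copy is updated by schedule, never by gradients", {
  vp <- tiny_vp()
  set.seed(3)
  S <- rand_state(8)
  S2 <- rand_state(8)
  target_before <- vp$target_par
  up <- hhvg:::.value_update(vp, adam_init(vp$net$par), S, rnorm(8), S2,
                             gamma = 0.9, lr = 1e-2)
  expect_identical(up$vp$target_par, target_before)
  expect_false(identical(up$vp$net$par, target_before))
})

test_that("the enumerated policy loss matches an independent per-action loop", {
  fm <- tiny_fm()
  mm_b <- tiny_mm(seed = 5)
  mm_a <- tiny_mm(seed = 6)
  vp <- tiny_vp()
  pp <- tiny_pp()
  set.seed(4)
  S <- rand_state(3)
  gamma <- 0.9
  got <- policy_loss(pp, fm, mm_b, mm_a, vp, S, gamma)
  acts <- action_grid()
  per_state <- sapply(seq_len(nrow(S)), function(i) {
    p <- policy_distribution(pp, S[i, ])
    q_b <- meta_predict(mm_b, S[i, ])
    q_a <- meta_predict(mm_a, S[i, ])
    g <- sapply(seq_len(121), function(k) {
      pb <- predict_forward(fm, S[i, ], acts[k, ])
      r <- gaussian_kl(pb, q_b, jitter = 0) - gaussian_kl(pb, q_a, jitter = 0)
      r + gamma * state_value(vp, pb$mean)
    })
    sum(p * g)
  })
  expect_equal(got, -mean(per_state), tolerance = 1e-8)
})

test_that("the enumerated expectation agrees with sampled action returns", {
  fm <- tiny_fm()
  mm_b <- tiny_mm(seed = 5)
  mm_a <- tiny_mm(seed = 6)
  vp <- tiny_vp()
  pp <- tiny_pp()
  s <- c(0.4, 0.3, 0.1, -0.1)
  G <- hhvg:::.action_returns_deval(fm, mm_b, mm_a, vp, matrix(s, 1, 4), 0.9)
  p <- policy_distribution(pp, s)
  exact <- sum(p * G[1, ])
  set.seed(11)
  idx <- sample.int(121, 1e5, replace = TRUE, prob = p)
  mc <- mean(G[1, idx])
  se <- sd(G[1, idx]) / sqrt(1e5)
  expect_lt(abs(mc - exact), 4 * se + 1e-12)
})

test_that("a value-gradient step moves probability toward the better action", {
  pp <- tiny_pp()
  pp$net <- zero_net(pp$net)  # uniform start
  s <- c(0.5, 0.5, 0, 0)
  G <- matrix(0, 1, 121)
  G[1, 8] <- 1  # action 7 (0-based) is worth 1, all others 0
  p0 <- policy_distribution(pp, s)
  up <- hhvg:::.policy_svg_update(pp, adam_init(pp$net$par), matrix(s, 1, 4),
                                  G, lr = 1e-2)
  p1 <- policy_distribution(up$pp, s)
  expect_gt(p1[8], p0[8])
  expect_lt(max(p1[-8]), p1[8])
})

test_that("REINFORCE loss and gradient behave as the score-function estimator", {
  pp <- tiny_pp()
  set.seed(5)
  S <- rand_state(4)
  a_idx <- c(0L, 60L, 120L, 5L)
  expect_equal(policy_gradient_loss(pp, S, a_idx, rep(0, 4)), 0)
  # zero rewards produce zero gradients: parameters do not move
  up0 <- hhvg:::.policy_reinforce_update(pp, adam_init(pp$net$par), S, a_idx,
                                         rep(0, 4), lr = 1e-2)
  expect_identical(up0$pp$net$par, pp$net$par)
  # hand-computed loss on a toy batch
  P <- policy_distribution(pp, S)
  R <- c(1, -0.5, 0.2, 0)
  by_hand <- -mean(log(P[cbind(1:4, a_idx + 1L)]) * R)
  expect_equal(policy_gradient_loss(pp, S, a_idx, R), by_hand)
  # positive reward on one executed action raises its probability
  pp0 <- pp
  pp0$net <- zero_net(pp0$net)
  up <- hhvg:::.policy_reinforce_update(pp0, adam_init(pp0$net$par),
                                        matrix(c(0.5, 0.5, 0, 0), 1, 4), 42L,
                                        1, lr = 1e-2)
  expect_gt(policy_distribution(up$pp, c(0.5, 0.5, 0, 0))[43], 1 / 121)
})
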