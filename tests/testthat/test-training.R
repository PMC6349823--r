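test_that("variant specs reproduce the pruning ladder", {
  cb <- make_variant("C/B")
  expect_true(cb$fm && cb$vf && cb$mm)
  expect_equal(cb$ap, "learned")
  expect_equal(cb$ir, "deval")
  cpe <- make_variant("C/PE")
  expect_false(cpe$mm)
  expect_equal(cpe$ir, "lp")
  irs <- make_variant("PG/IRS")
  expect_false(irs$vf)
  expect_equal(irs$ir, "replay")
  expect_equal(make_variant("PG/GR")$ir, "gauss")
  prw <- make_variant("P/RW")
  expect_equal(prw$ap, "random")
  expect_equal(prw$ir, "none")
  expect_false(make_variant("Oracle")$interactive)
  expect_error(make_variant("nope"), "unknown variant")
  # P/RW carries no policy/value/meta parameters
  agent <- agent_init(prw, run_config(width = 8, seed = 1))
  expect_null(agent$pp)
  expect_null(agent$vp)
  expect_null(agent$mm)
})

test_that("variants share identical initialisation where architectures coincide", {
  cfg <- run_config(width = 8, seed = 7)
  a1 <- agent_init(make_variant("C/B"), cfg)
  a2 <- agent_init(make_variant("P/RW"), cfg)
  a3 <- agent_init(make_variant("PG/GR"), cfg)
  expect_identical(a1$fm$net$par, a2$fm$net$par)
  expect_identical(a1$fm$net$par, a3$fm$net$par)
  expect_identical(a1$pp$net$par, a3$pp$net$par)
})

test_that("the DAP appends exactly one transition per step", {
  cfg <- run_config(T_dap = 10, batch = 4, policy_batch = 2, width = 8,
                    seed = 3)
  res <- run_dap("C/B", env_config(), cfg)
  expect_equal(buffer_size(res$buffer), 10)
  expect_equal(res$buffer$T0[1:10], 0:9)
  # stored transitions satisfy s' = step(s, a) under the run's config
  for (i in c(1, 5, 10))
    expect_equal(res$buffer$S2[i, ],
                 env_step(res$buffer$S[i, ], res$buffer$A[i], env_config()))
  # a C/B run emits one reward record set per step
  expect_equal(sort(unique(res$reward_db$t)), 0:9)
})

test_that("zero learning rates leave all parameters bitwise unchanged", {
  cfg <- run_config(T_dap = 5, batch = 4, policy_batch = 2, width = 8,
                    lr_model = 0, lr_policy = 0, lr_value = 0, seed = 5)
  init <- agent_init(make_variant("C/B"), cfg)
  res <- run_dap("C/B", env_config(), cfg)
  expect_identical(res$agent$fm$net$par, init$fm$net$par)
  expect_identical(res$agent$pp$net$par, init$pp$net$par)
  expect_identical(res$agent$vp$net$par, init$vp$net$par)
  expect_identical(res$agent$mm$mu$par, init$mm$mu$par)
  expect_equal(buffer_size(res$buffer), 5)
})

test_that("runs are reproducible given the seed", {
  cfg <- run_config(T_dap = 12, batch = 6, policy_batch = 2, width = 8,
                    seed = 11)
  r1 <- run_dap("C/B", env_config(), cfg)
  r2 <- run_dap("C/B", env_config(), cfg)
  expect_identical(r1$logs$fm_loss, r2$logs$fm_loss)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$agent$fm$net$par, r2$agent$fm$net$par)
})

test_that("the random-walk variant selects actions uniformly", {
  cfg <- run_config(T_dap = 1500, batch = 4, width = 8, seed = 13)
  res <- run_dap("P/RW", env_config(), cfg)
  tab <- tabulate(res$actions + 1L, nbins = 121)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("PG/IRS refuses to run without a reward database", {
  cfg <- run_config(T_dap = 3, batch = 2, width = 8, seed = 1)
  expect_error(run_dap("PG/IRS", env_config(), cfg), "C/B")
})

test_that("the plateau scheduler fires at 3000 and 6000 on a constant loss", {
  sched <- plateau_scheduler(lr = 1e-3, patience = 3000, factor = 0.1)
  for (e in 1:7000) sched <- plateau_update(sched, 1.0)
  expect_equal(sched$reductions, c(3000L, 6000L))
  expect_equal(sched$lr, 1e-3 * 0.01)
  # strictly decreasing loss never triggers a reduction
  sched2 <- plateau_scheduler(lr = 1e-3, patience = 10, factor = 0.1)
  for (e in 1:200) sched2 <- plateau_update(sched2, 1 / e)
  expect_length(sched2$reductions, 0)
  expect_equal(sched2$lr, 1e-3)
})

test_that("post-DAP refines the model without touching the environment", {
  cfg <- run_config(T_dap = 30, T_post = 40, batch = 8, width = 8, seed = 17,
                    lr_model = 1e-3)
  res <- run_dap("P/RW", env_config(), cfg)
  n0 <- buffer_size(res$buffer)
  pd <- run_post_dap(res$agent, res$buffer, cfg)
  expect_equal(buffer_size(res$buffer), n0)
  expect_length(pd$losses, 40)
  expect_lt(mean(tail(pd$losses, 5)), mean(head(pd$losses, 5)))
  expect_error(run_post_dap(res$agent, transition_buffer(10), cfg), "empty")
})
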