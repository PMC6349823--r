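# Desk-scale experiment harnesses: the ablation-ladder benchmark that
# reproduces the qualitative ordering of the full-scale study, and the
# self-reinforcement diagnostic contrasting interestingness-seeking with
# devaluation-progress policies.

#' Run the scaled ablation-ladder experiment
#'
#' For each seed, runs the DAP for C/B first (collecting its reward
#' database), then C/PE, PG/IRS (replaying that database), PG/GR and P/RW
#' under identical environment configuration, initial position and network
#' initialisation, plus the supervised Oracle on the grid dataset.  All
#' variants are scored on the same validation split of the oracle dataset.
#'
#' Defaults are the desk-scale study conditions: 2,000-step DAP, width-64
#' networks, a 5 x 5 x 3 x 3 x 5 x 5 oracle grid, three seeds.
#'
#' @param seeds integer run seeds.
#' @param env_cfg an [env_config()].
#' @param grid an [oracle_grid_spec()].
#' @param T_dap DAP length.
#' @param width network width.
#' @param batch,policy_batch batch sizes.
#' @param lr_model,lr_policy,lr_value learning rates at this scale.
#' @param gamma discount factor.
#' @param oracle_epochs supervised Oracle training epochs.
#' @param split_seed seed of the shared dataset split.
#' @param variants variant names to run (default: the full ladder).
#' @param verbose print progress.
#' @return data.frame with one row per (variant, seed): `percent_error`,
#'   `mse`, `terminal_cr`; the shared max-distance denominator is attached
#'   as attribute `max_dist`.
#' @export
ablation_experiment <- function(seeds = 1:3,
                                env_cfg = env_config(),
                                grid = oracle_grid_spec(n_pos = 5, n_vel = 3,
                                                        n_act = 5),
                                T_dap = 2000, width = 64, batch = 64,
                                policy_batch = 16, lr_model = 1e-3,
                                lr_policy = 3e-4, lr_value = 1e-3,
                                gamma = 0.9,
                                oracle_epochs = 4000, split_seed = 1,
                                variants = c("C/B", "C/PE", "PG/IRS",
                                             "PG/GR", "P/RW", "Oracle"),
                                verbose = FALSE) {
  dataset <- generate_oracle_dataset(grid, env_cfg)
  split <- split_dataset(nrow(dataset$S), seed = split_seed)
  max_dist <- max_pairwise_distance(dataset$S2[split$validation, , drop = FALSE])
  rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (seed in seeds) {
    cfg <- run_config(T_dap = T_dap, T_post = oracle_epochs, batch = batch,
                      policy_batch = policy_batch, lr_model = lr_model,
                      lr_policy = lr_policy, lr_value = lr_value,
                      gamma = gamma, width = width, seed = seed)
    db <- NULL
    for (v in variants) {
      t0 <- proc.time()[3]
      if (v == "Oracle") {
        tr <- train_oracle(dataset, split, cfg, epochs = oracle_epochs)
        err <- error_percentage(tr$fm, dataset, split$validation, max_dist)
        cr <- NA_real_
      } else {
        res <- run_dap(v, env_cfg, cfg,
                       replay_db = if (v == "PG/IRS") db else NULL)
        if (v == "C/B") db <- res$reward_db
        err <- error_percentage(res$agent$fm, dataset, split$validation,
                                max_dist)
        cr <- coverage_rate(res$states[, 1:2])[nrow(res$states)]
      }
      say("seed %d %-6s: %.3f%% error, CR %.3f (%.0fs)", seed, v,
          err$percent, cr, proc.time()[3] - t0)
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, seed = seed, percent_error = err$percent,
        mse = err$mse, terminal_cr = cr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "max_dist") <- max_dist
  out
}

#' Self-reinforcement diagnostic at a frozen state
#'
#' Alternates one devaluation (psi) update with one policy (phi) update at a
#' single state, with the forward model frozen.  With the devaluation
#' *objective* used directly as reward (`mode = "objective"`, the
#' interestingness-seeking ablation) the policy objective is linear in the
#' action distribution with near-static coefficients, so the alternation is
#' a self-reinforcing cycle that drives the policy toward a point mass.
#' With devaluation *progress* (`mode = "progress"`) the reward hovers
#' around the devaluation equilibrium and the policy retains entropy.
#'
#' @param s frozen state.
#' @param mode `"objective"` (reward = KL itself) or `"progress"`
#'   (reward = before-minus-after KL).
#' @param n_iter alternating update count.
#' @param width network width.
#' @param lr_psi Adam learning rate of the devaluation update.
#' @param lr_phi plain-gradient learning rate of the policy update; the
#'   policy step is deliberately non-adaptive so that the magnitude of the
#'   reward signal — the quantity the two modes differ in — matters.
#' @param seed network initialisation seed.
#' @return list with `entropy` (policy entropy per iteration, nats),
#'   `prob` (final action distribution), `mode`.
#' @export
policy_selfreinforcement <- function(s = c(0.5, 0.5, 0, 0),
                                     mode = c("objective", "progress"),
                                     n_iter = 2000, width = 32,
                                     lr_psi = 1e-3, lr_phi = 0.02,
                                     seed = 1) {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  fm <- forward_model(width, 2, seed = seed)
  mm <- meta_model(width, 2, seed = seed + 1L)
  pp <- policy_network(width, 2, seed = seed + 2L)
  mm_opts <- list(mu = adam_init(mm$mu$par), d = adam_init(mm$d$par),
                  u = adam_init(mm$u$par))
  S <- matrix(s, 1, 4)
  hd <- .fm_heads(fm, S)
  jac <- .jac_row(hd, 1)
  sigma2 <- fm$sigma_s^2
  entropy <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    p <- policy_distribution(pp, s)
    # psi update: minimise E_{a~pi} KL(P_a || Q)
    mo <- .mm_outputs(mm, S, keep_cache = TRUE)
    q <- list(mu = mo$mu[1, ], d = mo$d[1, ], u = mo$u[1, ], zd = mo$zd[1, ])
    ka <- .kl_actions(jac, s, sigma2, q, w = p)
    g_mu <- mlp_backward(mm$mu, mo$cache_mu, list(out = matrix(ka$gmu, 1)))
    g_d <- mlp_backward(mm$d, mo$cache_d, list(out = matrix(ka$gzd, 1)))
    g_u <- mlp_backward(mm$u, mo$cache_u, list(out = matrix(ka$gu, 1)))
    up <- adam_step(mm$mu$par, g_mu, mm_opts$mu, lr_psi)
    mm$mu$par <- up$par; mm_opts$mu <- up$opt
    up <- adam_step(mm$d$par, g_d, mm_opts$d, lr_psi)
    mm$d$par <- up$par; mm_opts$d <- up$opt
    up <- adam_step(mm$u$par, g_u, mm_opts$u, lr_psi)
    mm$u$par <- up$par; mm_opts$u <- up$opt
    # rewards under the post-update meta-model
    mo2 <- .mm_outputs(mm, S)
    ka2 <- .kl_actions(jac, s, sigma2,
                       list(mu = mo2$mu[1, ], d = mo2$d[1, ], u = mo2$u[1, ]))
    R <- if (mode == "objective") ka2$kl else ka$kl - ka2$kl
    # phi update on the frozen state (gamma = 0), plain gradient descent
    fw <- mlp_forward(pp$net, S, keep_cache = TRUE)
    pr <- .softmax_rows(fw$heads$logits)
    glogits <- -pr * (matrix(R, 1) - sum(pr * R))
    g <- mlp_backward(pp$net, fw$cache, list(logits = glogits))
    for (k in names(pp$net$par))
      pp$net$par[[k]] <- pp$net$par[[k]] - lr_phi * g[[k]]
    entropy[it] <- policy_entropy(policy_distribution(pp, s))
  }
  list(entropy = entropy, prob = policy_distribution(pp, s), mode = mode)
}

#' Monte-Carlo validation of the closed-form Gaussian KL
#'
#' Draws random belief pairs, estimates `E_p[log p - log q]` by Monte Carlo
#' and reports the closed-form value, the estimate and its standard error.
#'
#' @param n_pairs number of random belief pairs.
#' @param n_samples Monte-Carlo draws per pair.
#' @param dim belief dimension.
#' @param seed RNG seed.
#' @return data.frame with columns `closed_form`, `mc`, `se`.
#' @export
kl_mc_check <- function(n_pairs = 10, n_samples = 1e6, dim = 4, seed = 1) {
  set.seed(as.integer(seed))
  rbelief <- function() {
    M <- matrix(stats::rnorm(dim * dim, sd = 0.5), dim, dim)
    gaussian_belief(stats::rnorm(dim), crossprod(M) + 0.05 * diag(dim))
  }
  out <- data.frame(closed_form = numeric(n_pairs), mc = numeric(n_pairs),
                    se = numeric(n_pairs))
  for (i in seq_len(n_pairs)) {
    p <- rbelief()
    q <- rbelief()
    out$closed_form[i] <- gaussian_kl(p, q, jitter = 0)
    X <- sample_belief(p, n_samples)
    lp <- .dmvnorm_log(X, p$mean, p$cov)
    lq <- .dmvnorm_log(X, q$mean, q$cov)
    d <- lp - lq
    out$mc[i] <- mean(d)
    out$se[i] <- stats::sd(d) / sqrt(n_samples)
  }
  out
}

# Log-density of rows of X under N(mu, S).
.dmvnorm_log <- function(X, mu, S) {
  k <- length(mu)
  R <- chol(S)
  D <- X - matrix(mu, nrow(X), k, byrow = TRUE)
  W <- backsolve(R, t(D), transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(W * W))
}
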