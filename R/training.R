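# Orchestration: Data Accumulation Phase (DAP), post-DAP refinement, the
# replay database, and the model-pruning ladder of agent variants.
#
# Variant ladder (components: FM forward model, AP action policy, IR
# intrinsic reward, VF value function, MM meta-model):
#   C/B    : FM AP IR VF MM  — devaluation progress reward, SVG policy
#   C/PE   : FM AP IR VF     — learning-progress reward, SVG policy
#   PG/IRS : FM AP IR        — replayed C/B rewards, REINFORCE
#   PG/GR  : FM AP           — Gaussian surrogate reward, REINFORCE
#   P/RW   : FM              — uniform random policy (epsilon-greedy, eps = 1)
#   Oracle : FM              — trained on the grid dataset, no interaction

VARIANT_NAMES <- c("C/B", "C/PE", "PG/IRS", "PG/GR", "P/RW", "Oracle")

#' Variant specification from the model-pruning ladder
#'
#' @param name one of `"C/B"`, `"C/PE"`, `"PG/IRS"`, `"PG/GR"`, `"P/RW"`,
#'   `"Oracle"`.
#' @return object of class `hhvg_variant` with component flags: `fm`
#'   (logical), `ap` (`"learned"`, `"random"` or `"absent"`), `ir`
#'   (`"deval"`, `"lp"`, `"replay"`, `"gauss"` or `"none"`), `vf`, `mm`
#'   (logicals), `interactive` (FALSE for Oracle).
#' @export
make_variant <- function(name) {
  spec <- switch(name,
    "C/B"    = list(ap = "learned", ir = "deval",  vf = TRUE,  mm = TRUE,
                    interactive = TRUE),
    "C/PE"   = list(ap = "learned", ir = "lp",     vf = TRUE,  mm = FALSE,
                    interactive = TRUE),
    "PG/IRS" = list(ap = "learned", ir = "replay", vf = FALSE, mm = FALSE,
                    interactive = TRUE),
    "PG/GR"  = list(ap = "learned", ir = "gauss",  vf = FALSE, mm = FALSE,
                    interactive = TRUE),
    "P/RW"   = list(ap = "random",  ir = "none",   vf = FALSE, mm = FALSE,
                    interactive = TRUE),
    "Oracle" = list(ap = "absent",  ir = "none",   vf = FALSE, mm = FALSE,
                    interactive = FALSE),
    stop("unknown variant: ", name)
  )
  structure(c(list(name = name, fm = TRUE), spec), class = "hhvg_variant")
}

#' Run hyperparameters
#'
#' Defaults follow the full-scale study conditions (30,000-step DAP,
#' 30,000-epoch post-DAP, width-512 networks, batch 128, constant model
#' learning rates during DAP, plateau scheduling post-DAP).  Scaled-down
#' experiments override `T_dap`, `width` and friends.
#'
#' @param T_dap interactive steps of the Data Accumulation Phase.
#' @param T_post action-free refinement epochs (one optimiser step on one
#'   sampled batch per epoch).
#' @param batch replay batch size per step.
#' @param policy_batch states per SVG policy update (exact 121-action
#'   enumeration per state makes this the costly part).
#' @param lr_model,lr_policy,lr_value Adam learning rates.
#' @param gamma discount factor.
#' @param target_sync hard-copy period (gradient steps) of the value target.
#' @param width,depth_fm,depth_mm,depth_pv network sizes.
#' @param sigma_s base state standard deviation of the forward model.
#' @param o_dim forward-model offset head size (4 or 1).
#' @param replay_capacity transition buffer capacity (default: unbounded,
#'   i.e. `T_dap`).
#' @param recent_frac fraction of each training batch drawn from the most
#'   recent 200 transitions (0 = plain uniform replay).  Recency keeps the
#'   meta-model tracking the *current* policy's outcome marginal, which is
#'   what devaluation is meant to devalue.
#' @param policy_decay decoupled per-step weight decay on the policy logit
#'   head.  Bounds the logits so the policy cannot saturate irreversibly:
#'   when the intrinsic reward signal equilibrates (assimilated outcomes),
#'   the decay relaxes the action distribution back toward uniform, giving
#'   the "bored" agent its restlessness back (0 disables).
#' @param warmup steps of uniform action selection (and no policy updates)
#'   before the learned policy takes over, giving the models signal before
#'   the policy starts consuming it (0 disables).
#' @param epsilon exploration floor of the behaviour policy: with this
#'   probability the executed action is drawn uniformly instead of from
#'   the learned policy (the random-walk variant corresponds to 1).
#' @param plateau_patience,plateau_factor post-DAP learning-rate schedule.
#' @param seed run seed; component initialisations are derived from it so
#'   that all variants of one experiment share identical initial networks.
#' @return object of class `hhvg_run_config`.
#' @export
run_config <- function(T_dap = 30000, T_post = 30000, batch = 128,
                       policy_batch = 16, lr_model = 1e-4, lr_policy = 1e-4,
                       lr_value = 1e-4, gamma = 0.9, target_sync = 100,
                       width = 512, depth_fm = 4, depth_mm = 3, depth_pv = 4,
                       sigma_s = 0.01, o_dim = 4, replay_capacity = NULL,
                       recent_frac = 0, policy_decay = 0, warmup = 0,
                       epsilon = 0,
                       plateau_patience = 3000, plateau_factor = 0.1,
                       seed = 1) {
  structure(as.list(environment()), class = "hhvg_run_config")
}

#' Initialise an agent's networks for a variant
#'
#' Component seeds are derived from `cfg$seed` identically for every
#' variant, so architectures that coincide across variants start from
#' bitwise-identical parameters.
#'
#' @param variant an [make_variant()] spec.
#' @param cfg an [run_config()].
#' @return object of class `hhvg_agent`.
#' @export
agent_init <- function(variant, cfg) {
  stopifnot(inherits(variant, "hhvg_variant"))
  s0 <- as.integer(cfg$seed)
  agent <- list(variant = variant,
                fm = forward_model(cfg$width, cfg$depth_fm, cfg$sigma_s,
                                   cfg$o_dim, seed = s0 + 11L))
  agent$fm_opt <- adam_init(agent$fm$net$par)
  if (variant$ap == "learned") {
    agent$pp <- policy_network(cfg$width, cfg$depth_pv, seed = s0 + 12L)
    agent$pp_opt <- adam_init(agent$pp$net$par)
  }
  if (variant$vf) {
    agent$vp <- value_network(cfg$width, cfg$depth_pv, seed = s0 + 13L)
    agent$vp_opt <- adam_init(agent$vp$net$par)
    agent$value_steps <- 0L
  }
  if (variant$mm) {
    agent$mm <- meta_model(cfg$width, cfg$depth_mm, seed = s0 + 14L)
    agent$mm_opts <- list(mu = adam_init(agent$mm$mu$par),
                          d = adam_init(agent$mm$d$par),
                          u = adam_init(agent$mm$u$par))
  }
  structure(agent, class = "hhvg_agent")
}

# ---- transition buffer (environment-backed, append-only during DAP) --------

#' Create a transition replay buffer
#' @param capacity maximum number of transitions (FIFO eviction beyond it).
#' @return environment of class `hhvg_buffer` with preallocated storage.
#' @export
transition_buffer <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$S <- matrix(NA_real_, capacity, 4)
  e$A <- integer(capacity)
  e$S2 <- matrix(NA_real_, capacity, 4)
  e$T0 <- integer(capacity)
  e$n <- 0L
  e$capacity <- as.integer(capacity)
  class(e) <- "hhvg_buffer"
  e
}

#' Append one transition (mutates the buffer in place)
#' @param buf a [transition_buffer()].
#' @param s,a,s2 transition; `t` its 0-based step index.
#' @export
buffer_append <- function(buf, t, s, a, s2) {
  if (buf$n < buf$capacity) {
    buf$n <- buf$n + 1L
    i <- buf$n
  } else {
    i <- (t %% buf$capacity) + 1L  # FIFO overwrite
  }
  buf$S[i, ] <- s
  buf$A[i] <- a
  buf$S2[i, ] <- s2
  buf$T0[i] <- t
  invisible(buf)
}

#' Number of stored transitions
#' @param buf a [transition_buffer()].
#' @export
buffer_size <- function(buf) buf$n

# Uniform batch without replacement (whole batch if the buffer is smaller).
# With recent_frac > 0, that fraction of the batch is drawn from the most
# recent `recent_window` transitions instead: devaluation then tracks the
# behaving policy instead of the buffer's age distribution, which is what
# closes the boredom -> policy-shift cycle within short runs.
.buffer_sample <- function(buf, batch, recent_frac = 0, recent_window = 200L) {
  if (buf$n <= batch) {
    idx <- seq_len(buf$n)
  } else if (recent_frac <= 0) {
    idx <- sample.int(buf$n, batch)
  } else {
    n_rec <- min(round(recent_frac * batch), buf$n)
    lo <- max(1L, buf$n - as.integer(recent_window) + 1L)
    recent <- lo:buf$n
    idx_rec <- recent[sample.int(length(recent), min(n_rec, length(recent)))]
    idx_uni <- sample.int(buf$n, batch - length(idx_rec))
    idx <- c(idx_rec, idx_uni)
  }
  list(S = buf$S[idx, , drop = FALSE], A = buf$A[idx],
       S2 = buf$S2[idx, , drop = FALSE], T0 = buf$T0[idx])
}

# ---- DAP -------------------------------------------------------------------

#' One step of the Data Accumulation Phase
#'
#' Fixed order: action selection, environment step, transition append,
#' batch sampling, forward-model update, meta-model update (+ devaluation
#' progress), variant reward, value update, policy update.
#'
#' @param agent an [agent_init()] agent.
#' @param state current environment state.
#' @param t 0-based step index.
#' @param buffer a [transition_buffer()] (mutated in place).
#' @param env_cfg an [env_config()].
#' @param cfg an [run_config()].
#' @param replay_db reward database (required by PG/IRS).
#' @param out_db reward database being populated (C/B), or NULL.
#' @return list with `agent`, `state` (next state), `out_db` and `log`
#'   (named numerics: fm_loss, reward_mean, entropy).
#' @export
dap_step <- function(agent, state, t, buffer, env_cfg, cfg,
                     replay_db = NULL, out_db = NULL) {
  variant <- agent$variant
  if (variant$ir == "replay" && is.null(replay_db))
    stop("PG/IRS requires a reward database from a C/B run")
  warm <- t < cfg$warmup
  # (1) action selection (epsilon floor keeps the behaviour policy
  # stochastic even when the learned policy concentrates)
  if (variant$ap == "learned" && !warm) {
    p <- policy_distribution(agent$pp, state)
    ent <- policy_entropy(p)
    if (cfg$epsilon > 0 && stats::runif(1) < cfg$epsilon)
      a <- sample.int(N_ACTIONS, 1) - 1L
    else
      a <- sample.int(N_ACTIONS, 1, prob = p) - 1L
  } else {
    a <- sample.int(N_ACTIONS, 1) - 1L
    ent <- if (variant$ap == "learned")
      policy_entropy(policy_distribution(agent$pp, state)) else log(N_ACTIONS)
  }
  # (2) environment step, (3) append
  s2 <- env_step(state, a, env_cfg)
  buffer_append(buffer, t, state, a, s2)
  # (4) batch
  b <- .buffer_sample(buffer, cfg$batch, cfg$recent_frac)
  Acc <- action_accel(b$A)
  # (5) forward-model update
  fm_before <- agent$fm
  upf <- .fm_update(agent$fm, agent$fm_opt, b$S, Acc, b$S2, cfg$lr_model)
  agent$fm <- upf$fm
  agent$fm_opt <- upf$opt
  fm_loss <- mean(upf$sqerr_before)
  R <- NULL
  mm_before <- NULL
  # (6) meta-model update and devaluation progress
  if (variant$mm) {
    mm_before <- agent$mm
    fmout <- .fm_predict_batch(agent$fm, b$S, Acc)
    upm <- .mm_update(agent$mm, agent$mm_opts, fmout, b$S, cfg$lr_model,
                      agent$fm$sigma_s^2)
    agent$mm <- upm$mm
    agent$mm_opts <- upm$opts
    kl_after <- .kl_pairs(fmout, .mm_outputs(agent$mm, b$S),
                          agent$fm$sigma_s^2)$kl
    R <- upm$kl_before - kl_after
    if (!is.null(out_db)) out_db <- reward_db_add(out_db, t, R)
  }
  # (7) variant reward
  if (variant$ir == "lp") {
    e_after <- rowSums((b$S2 - .fm_predict_batch(agent$fm, b$S, Acc)$mean)^2)
    R <- upf$sqerr_before - e_after
  } else if (variant$ir == "replay") {
    R <- replay_reward(replay_db, t, nrow(b$S))
  } else if (variant$ir == "gauss") {
    R <- surrogate_reward(nrow(b$S))
  }
  # (8) value update
  if (variant$vf) {
    upv <- .value_update(agent$vp, agent$vp_opt, b$S, R, b$S2, cfg$gamma,
                         cfg$lr_value)
    agent$vp <- upv$vp
    agent$vp_opt <- upv$opt
    agent$value_steps <- agent$value_steps + 1L
    if (agent$value_steps %% cfg$target_sync == 0L)
      agent$vp$target_par <- agent$vp$net$par
  }
  # (9) policy update (suspended during warmup)
  if (variant$ap == "learned" && !warm) {
    if (variant$ir %in% c("deval", "lp")) {
      np <- min(cfg$policy_batch, nrow(b$S))
      Sp <- b$S[seq_len(np), , drop = FALSE]
      G <- if (variant$ir == "deval")
        .action_returns_deval(agent$fm, mm_before, agent$mm, agent$vp,
                              Sp, cfg$gamma)
      else
        .action_returns_lp(fm_before, agent$fm, agent$vp, Sp, cfg$gamma)
      upp <- .policy_svg_update(agent$pp, agent$pp_opt, Sp, G, cfg$lr_policy,
                                decay = cfg$policy_decay)
    } else {
      upp <- .policy_reinforce_update(agent$pp, agent$pp_opt, b$S, b$A, R,
                                      cfg$lr_policy,
                                      decay = cfg$policy_decay)
    }
    agent$pp <- upp$pp
    agent$pp_opt <- upp$opt
  }
  list(agent = agent, state = s2, action = a, out_db = out_db,
       log = c(fm_loss = fm_loss,
               reward_mean = if (is.null(R)) NA_real_ else mean(R),
               entropy = ent))
}

#' Run the Data Accumulation Phase for one variant
#'
#' Exactly `cfg$T_dap` steps of [dap_step()] from [env_reset()];
#' reproducible given `cfg$seed`.
#'
#' @param variant a variant name or [make_variant()] spec.
#' @param env_cfg an [env_config()].
#' @param cfg an [run_config()].
#' @param replay_db reward database (PG/IRS only).
#' @return list with `agent`, `buffer`, `states` ((T+1) x 4 trajectory),
#'   `actions`, `logs` (data.frame), and `reward_db` (C/B runs).
#' @export
run_dap <- function(variant, env_cfg, cfg, replay_db = NULL) {
  if (is.character(variant)) variant <- make_variant(variant)
  if (!variant$interactive)
    stop("the Oracle variant does not interact; use train_oracle()")
  set.seed(as.integer(cfg$seed))
  agent <- agent_init(variant, cfg)
  capacity <- if (is.null(cfg$replay_capacity)) cfg$T_dap else cfg$replay_capacity
  buffer <- transition_buffer(capacity)
  out_db <- if (variant$ir == "deval") reward_db() else NULL
  state <- env_reset(env_cfg)
  states <- matrix(NA_real_, cfg$T_dap + 1, 4)
  states[1, ] <- state
  actions <- integer(cfg$T_dap)
  logs <- matrix(NA_real_, cfg$T_dap, 3,
                 dimnames = list(NULL, c("fm_loss", "reward_mean", "entropy")))
  for (t in seq_len(cfg$T_dap) - 1L) {
    st <- dap_step(agent, state, t, buffer, env_cfg, cfg,
                   replay_db = replay_db, out_db = out_db)
    agent <- st$agent
    state <- st$state
    out_db <- st$out_db
    states[t + 2, ] <- state
    actions[t + 1] <- st$action
    logs[t + 1, ] <- st$log
  }
  list(agent = agent, buffer = buffer, states = states, actions = actions,
       logs = as.data.frame(logs), reward_db = out_db)
}

# ---- plateau learning-rate scheduler ---------------------------------------

#' Create a reduce-on-plateau learning-rate scheduler
#'
#' The monitored loss is checked once per epoch; when it fails to improve on
#' the best value seen for `patience` consecutive epochs the learning rate
#' is multiplied by `factor`.  The first observed loss initialises the best
#' value and opens the plateau window (so a constant loss sequence triggers
#' reductions exactly at epochs `patience`, `2 * patience`, ...).
#'
#' @param lr initial learning rate.
#' @param patience plateau length in epochs (default 3000).
#' @param factor multiplicative reduction (default 0.1).
#' @return scheduler state for [plateau_update()].
#' @export
plateau_scheduler <- function(lr, patience = 3000, factor = 0.1) {
  list(lr = lr, patience = as.integer(patience), factor = factor,
       best = Inf, wait = 0L, first = TRUE, reductions = integer(0),
       epoch = 0L)
}

#' Advance the plateau scheduler by one epoch
#' @param sched scheduler state.
#' @param loss monitored loss of this epoch.
#' @return updated scheduler state (fields `lr`, `reductions` = epochs at
#'   which the rate was reduced).
#' @export
plateau_update <- function(sched, loss) {
  sched$epoch <- sched$epoch + 1L
  if (sched$first) {
    sched$best <- loss
    sched$wait <- 1L
    sched$first <- FALSE
  } else if (loss < sched$best) {
    sched$best <- loss
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
  }
  if (sched$wait >= sched$patience) {
    sched$lr <- sched$lr * sched$factor
    sched$wait <- 0L
    sched$reductions <- c(sched$reductions, sched$epoch)
  }
  sched
}

#' Post-DAP action-free refinement of the forward model
#'
#' `cfg$T_post` epochs of forward-model-only training on the frozen buffer
#' (one Adam step on one uniformly sampled batch per epoch); no environment
#' interaction occurs.  The plateau rule monitors the training loss on the
#' agent's own buffer.
#'
#' @param agent agent holding the forward model (or a bare
#'   [forward_model()]).
#' @param buffer the frozen DAP [transition_buffer()].
#' @param cfg an [run_config()].
#' @return list with `fm`, `losses` (per epoch), `lr_trace`, `scheduler`.
#' @export
run_post_dap <- function(agent, buffer, cfg) {
  if (buffer_size(buffer) == 0) stop("empty buffer: run the DAP first")
  fm <- if (inherits(agent, "hhvg_forward_model")) agent else agent$fm
  opt <- adam_init(fm$net$par)
  sched <- plateau_scheduler(cfg$lr_model, cfg$plateau_patience,
                             cfg$plateau_factor)
  losses <- numeric(cfg$T_post)
  lr_trace <- numeric(cfg$T_post)
  n0 <- buffer_size(buffer)
  for (e in seq_len(cfg$T_post)) {
    b <- .buffer_sample(buffer, cfg$batch)
    up <- .fm_update(fm, opt, b$S, action_accel(b$A), b$S2, sched$lr)
    fm <- up$fm
    opt <- up$opt
    losses[e] <- mean(up$sqerr_before)
    sched <- plateau_update(sched, losses[e])
    lr_trace[e] <- sched$lr
  }
  stopifnot(buffer_size(buffer) == n0)  # frozen buffer, no interaction
  list(fm = fm, losses = losses, lr_trace = lr_trace, scheduler = sched)
}

#' Save / load an agent checkpoint
#' @param agent an `hhvg_agent` (or any model object).
#' @param path file path (RDS archive of arrays + metadata).
#' @export
save_checkpoint <- function(agent, path) {
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
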