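# Categorical action policy over the 121-action grid, state-value function
# with fitted policy evaluation (target network), and the two policy
# objectives: the stochastic-value-gradient loss with the expectation over
# actions computed exactly by enumeration, and the REINFORCE loss used by
# the pruned PG variants.

#' Create a policy network (121 logits)
#'
#' Four ReLU layers + single-layer residual connection + linear output;
#' outputs are logits of a categorical distribution over the action grid.
#' @param width hidden width (full-scale configuration: 512).
#' @param depth ReLU layers (default 4).
#' @param seed reproducible initialisation.
#' @return object of class `hhvg_policy`.
#' @export
policy_network <- function(width = 512, depth = 4, seed = NULL) {
  structure(list(net = mlp_init(4, width, depth, c(logits = N_ACTIONS),
                                seed = seed)),
            class = "hhvg_policy")
}

#' Create a state-value network with a frozen target copy
#'
#' The target copy is synchronised by schedule only (hard copy), never by
#' gradients.
#' @inheritParams policy_network
#' @return object of class `hhvg_value` with fields `net` and `target_par`.
#' @export
value_network <- function(width = 512, depth = 4, seed = NULL) {
  net <- mlp_init(4, width, depth, c(v = 1L), seed = seed)
  structure(list(net = net, target_par = net$par), class = "hhvg_value")
}

.softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

#' Action probabilities of the policy at given states
#' @param pp a [policy_network()].
#' @param s length-4 state or n x 4 matrix.
#' @return probability vector over the 121 actions (or n x 121 matrix).
#' @export
policy_distribution <- function(pp, s) {
  S <- if (is.null(dim(s))) matrix(s, 1, 4) else s
  P <- .softmax_rows(mlp_forward(pp$net, S)$heads$logits)
  if (is.null(dim(s))) drop(P) else P
}

#' Shannon entropy of a probability vector (nats)
#' @param p probability vector (or matrix of row distributions).
#' @return entropy value(s).
#' @export
policy_entropy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  drop(-rowSums(ifelse(p > 0, p * log(p), 0)))
}

#' State values
#' @param vp a [value_network()].
#' @param s state or state matrix.
#' @param target use the frozen target parameters.
#' @return numeric value(s).
#' @export
state_value <- function(vp, s, target = FALSE) {
  S <- if (is.null(dim(s))) matrix(s, 1, 4) else s
  net <- vp$net
  if (target) net$par <- vp$target_par
  drop(mlp_forward(net, S)$heads$v)
}

#' Fitted-policy-evaluation value loss
#'
#' Mean squared Bellman residual `||y - v(s)||^2` with the bootstrapped
#' target `y = R + gamma * v(s'; target)` treated as a constant (no
#' gradient flows into the target copy).
#'
#' @param vp a [value_network()].
#' @param S,S2 state and next-state matrices (n x 4).
#' @param R per-transition intrinsic rewards.
#' @param gamma discount factor in \[0, 1\].
#' @return scalar loss.
#' @export
value_loss <- function(vp, S, R, S2, gamma) {
  y <- R + gamma * state_value(vp, S2, target = TRUE)
  mean((y - state_value(vp, S))^2)
}

# Gradient step on the value network; target fixed.
.value_update <- function(vp, opt, S, R, S2, gamma, lr) {
  y <- R + gamma * state_value(vp, S2, target = TRUE)
  fw <- mlp_forward(vp$net, S, keep_cache = TRUE)
  v <- drop(fw$heads$v)
  gv <- matrix(2 * (v - y) / length(y), ncol = 1)
  g <- mlp_backward(vp$net, fw$cache, list(v = gv))
  up <- adam_step(vp$net$par, g, opt, lr)
  vp$net$par <- up$par
  list(vp = vp, opt = up$opt, loss = mean((y - v)^2))
}

#' Value-gradient policy loss with exact action enumeration
#'
#' `L(phi) = -mean_s sum_a pi(a|s; phi) [R(a, s) + gamma v(f(a, s); nu)]`
#' where the intrinsic reward of every candidate action is the devaluation
#' progress across the supplied meta-model checkpoints, and the next state
#' is the forward-model mean (the environment is deterministic).  Gradients
#' flow to phi only.
#'
#' @param pp a [policy_network()].
#' @param fm forward model (theta, fixed).
#' @param mm_before,mm_after meta-model checkpoints around one devaluation
#'   update.
#' @param vp value network (nu, fixed).
#' @param S n x 4 batch of states.
#' @param gamma discount factor.
#' @return scalar loss (batch mean).
#' @export
policy_loss <- function(pp, fm, mm_before, mm_after, vp, S, gamma) {
  G <- .action_returns_deval(fm, mm_before, mm_after, vp, S, gamma)
  P <- policy_distribution(pp, S)
  if (is.null(dim(P))) P <- matrix(P, 1)
  -mean(rowSums(P * G))
}

# Per-state x per-action returns R(a, s) + gamma v(f(a, s)) with devaluation
# progress rewards (C/B).
.action_returns_deval <- function(fm, mm_before, mm_after, vp, S, gamma,
                                  acts = action_grid()) {
  n <- nrow(S)
  hd <- .fm_heads(fm, S)
  qb <- .mm_outputs(mm_before, S)
  qa <- .mm_outputs(mm_after, S)
  s2 <- fm$sigma_s^2
  G <- matrix(0, n, nrow(acts))
  means <- vector("list", n)
  for (i in seq_len(n)) {
    jac <- .jac_row(hd, i)
    kb <- .kl_actions(jac, S[i, ], s2,
                      list(mu = qb$mu[i, ], d = qb$d[i, ], u = qb$u[i, ]), acts)
    ka <- .kl_actions(jac, S[i, ], s2,
                      list(mu = qa$mu[i, ], d = qa$d[i, ], u = qa$u[i, ]), acts)
    G[i, ] <- kb$kl - ka$kl
    means[[i]] <- ka$mean
  }
  if (gamma > 0) {
    V <- state_value(vp, do.call(rbind, means))
    G <- G + gamma * matrix(V, n, nrow(acts), byrow = TRUE)
  }
  G
}

# Per-state x per-action returns for C/PE.  The learning-progress reward
# needs the realised next state, which is unobserved for non-executed
# actions, so the policy's immediate-reward term is zeroed and the returns
# are carried entirely by the learned value function, gamma v(f(a, s)):
# the value network is trained on executed-transition learning progress and
# so propagates the same reward signal one step ahead.
.action_returns_lp <- function(fm_before, fm_after, vp, S, gamma,
                               acts = action_grid()) {
  n <- nrow(S)
  hd_a <- .fm_heads(fm_after, S)
  means <- vector("list", n)
  for (i in seq_len(n))
    means[[i]] <- .action_means(.jac_row(hd_a, i), S[i, ], acts)
  V <- state_value(vp, do.call(rbind, means))
  gamma * matrix(V, n, nrow(acts), byrow = TRUE)
}

# Forward-model means for all actions at one state (jac from .jac_row).
.action_means <- function(jac, s, acts = action_grid()) {
  n_a <- nrow(acts)
  Jflat <- matrix(as.vector(jac$A), n_a, 16, byrow = TRUE) +
    outer(acts[, 1], as.vector(jac$B1)) + outer(acts[, 2], as.vector(jac$B2))
  mu <- matrix(0, n_a, 4)
  for (i in 1:4) {
    acc_i <- jac$o[i] + jac$C[i, 1] * acts[, 1] + jac$C[i, 2] * acts[, 2]
    for (j in 1:4) acc_i <- acc_i + Jflat[, (j - 1) * 4 + i] * s[j]
    mu[, i] <- acc_i
  }
  mu
}

# Gradient step on phi minimising -mean_s sum_a pi_a G_a for a precomputed
# return matrix G (n x 121); G is treated as a constant.  Adam by default
# (sgd = TRUE gives a plain, magnitude-sensitive step, used by the
# self-reinforcement diagnostic where reward magnitude is the point).
.policy_svg_update <- function(pp, opt, S, G, lr, sgd = FALSE, decay = 0) {
  fw <- mlp_forward(pp$net, S, keep_cache = TRUE)
  P <- .softmax_rows(fw$heads$logits)
  n <- nrow(S)
  gbar <- rowSums(P * G)
  glogits <- -P * (G - gbar) / n
  g <- mlp_backward(pp$net, fw$cache, list(logits = glogits))
  if (sgd) {
    for (k in names(pp$net$par))
      pp$net$par[[k]] <- pp$net$par[[k]] - lr * g[[k]]
  } else {
    up <- adam_step(pp$net$par, g, opt, lr)
    pp$net$par <- up$par
    opt <- up$opt
  }
  if (decay > 0) {  # decoupled decay on the logit head bounds the logits,
    pp$net$par$W_logits <- pp$net$par$W_logits * (1 - decay)  # relaxing the
    pp$net$par$b_logits <- pp$net$par$b_logits * (1 - decay)  # policy toward
  }                 # uniform once the reward signal equilibrates
  list(pp = pp, opt = opt, loss = -mean(gbar))
}

#' REINFORCE policy-gradient loss
#'
#' `L(phi) = -mean_i [log pi(a_i | s_i; phi) * R_i]` over executed actions
#' with their rewards treated as constants (PG/IRS and PG/GR variants).
#'
#' @param pp a [policy_network()].
#' @param S n x 4 batch of states.
#' @param a_idx executed 0-based action indices.
#' @param R per-sample rewards.
#' @return scalar loss.
#' @export
policy_gradient_loss <- function(pp, S, a_idx, R) {
  P <- policy_distribution(pp, S)
  if (is.null(dim(P))) P <- matrix(P, 1)
  lp <- log(pmax(P[cbind(seq_len(nrow(P)), a_idx + 1L)], 1e-300))
  -mean(lp * R)
}

.policy_reinforce_update <- function(pp, opt, S, a_idx, R, lr, sgd = FALSE,
                                     decay = 0) {
  fw <- mlp_forward(pp$net, S, keep_cache = TRUE)
  P <- .softmax_rows(fw$heads$logits)
  n <- nrow(S)
  onehot <- matrix(0, n, ncol(P))
  onehot[cbind(seq_len(n), a_idx + 1L)] <- 1
  glogits <- -(onehot - P) * R / n
  g <- mlp_backward(pp$net, fw$cache, list(logits = glogits))
  if (sgd) {
    for (k in names(pp$net$par))
      pp$net$par[[k]] <- pp$net$par[[k]] - lr * g[[k]]
  } else {
    up <- adam_step(pp$net$par, g, opt, lr)
    pp$net$par <- up$par
    opt <- up$opt
  }
  if (decay > 0) {
    pp$net$par$W_logits <- pp$net$par$W_logits * (1 - decay)
    pp$net$par$b_logits <- pp$net$par$b_logits * (1 - decay)
  }
  lp <- log(pmax(P[cbind(seq_len(n), a_idx + 1L)], 1e-300))
  list(pp = pp, opt = opt, loss = -mean(lp * R))
}
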