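# Deterministic 2D attractor/repeller arena in the Mountain-Car lineage.
# State is (x, y, vx, vy); positions live in the unit square, velocities are
# unbounded.  Actions are accelerations from an 11 x 11 grid on [-2, 2]^2 and
# are modified by the force field of the attractor/repeller sources.

N_ACTION_LEVELS <- 11L
N_ACTIONS <- N_ACTION_LEVELS^2  # 121

#' Acceleration levels of the action grid
#' @return 11 evenly spaced values on \[-2, 2\].
#' @export
action_levels <- function() seq(-2, 2, length.out = N_ACTION_LEVELS)

#' The full 121-row action grid
#'
#' Row `i` holds the (ax, ay) acceleration pair of action index `i - 1`;
#' action indices are 0-based in \[0, 120\].  The x level varies fastest:
#' index = iy * 11 + ix with levels `action_levels()[ix + 1]` etc.
#' @return 121 x 2 numeric matrix with columns `ax`, `ay`.
#' @export
action_grid <- function() {
  lv <- action_levels()
  g <- cbind(ax = rep(lv, times = N_ACTION_LEVELS),
             ay = rep(lv, each = N_ACTION_LEVELS))
  g
}

#' Acceleration pair of an action index
#' @param action_index integer vector, values in \[0, 120\].
#' @return length(action_index) x 2 matrix of accelerations.
#' @export
action_accel <- function(action_index) {
  if (any(!is.finite(action_index)) ||
      any(action_index < 0L) || any(action_index > N_ACTIONS - 1L) ||
      any(action_index != floor(action_index)))
    stop("action_index must be an integer in [0, 120]")
  action_grid()[action_index + 1L, , drop = FALSE]
}

#' Environment configuration
#'
#' One attractor and several repellers exert a smooth, radially symmetric
#' force with Gaussian profile: a source at position `c` with strength `k`
#' contributes `+/- k * exp(-r^2 / (2 * sigma_f^2)) * (c - p) / sigma_f` at
#' position `p` (`+` toward the attractor, `-` away from a repeller).  The
#' force is zero at the source centre, peaks at distance `sigma_f`, and decays
#' smoothly; it is everywhere differentiable.
#'
#' The default layout has one attractor in the lower-right region (a
#' potential well deep enough, and close enough to the boundary's
#' velocity-zeroing dissipation, to capture an undirected random walker,
#' while persistent directed acceleration can still escape it) and three
#' repellers across the upper half whose cores exert more force than the
#' strongest action and are therefore essentially inaccessible to agents.
#' The start marker sits just outside the attractor core; the layout is
#' shared by all runs of an experiment.
#'
#' @param attractors list of `list(pos = c(x, y), strength = k)`.
#' @param repellers list of the same shape.
#' @param sigma_f decay scale of the force profile (positions units).
#' @param force_scale global multiplier on the field force.
#' @param dt explicit-Euler integration step.
#' @param damping optional velocity damping coefficient (default 0).
#' @param initial_position start position of every run.
#' @param boundary `"slide"` zeroes only the violating axis' velocity
#'   (tangential motion survives, so the agent can slide along walls);
#'   `"stop"` zeroes both components on any boundary hit.
#' @return object of class `hhvg_env_config`.
#' @export
env_config <- function(attractors = list(list(pos = c(0.70, 0.18), strength = 4.0)),
                       repellers = list(list(pos = c(0.20, 0.70), strength = 4.0),
                                        list(pos = c(0.55, 0.85), strength = 4.0),
                                        list(pos = c(0.85, 0.70), strength = 4.0)),
                       sigma_f = 0.35,
                       force_scale = 1.0,
                       dt = 0.05,
                       damping = 0.0,
                       initial_position = c(0.65, 0.15),
                       boundary = c("slide", "stop")) {
  boundary <- match.arg(boundary)
  stopifnot(is.finite(sigma_f), sigma_f > 0, is.finite(dt), dt > 0,
            is.finite(force_scale), is.finite(damping), damping >= 0,
            length(initial_position) == 2,
            all(initial_position >= 0 & initial_position <= 1))
  as_mat <- function(src) {
    if (length(src) == 0)
      return(list(pos = matrix(numeric(0), 0, 2), strength = numeric(0)))
    pos <- t(vapply(src, function(s) as.numeric(s$pos), numeric(2)))
    k <- vapply(src, function(s) as.numeric(s$strength), numeric(1))
    stopifnot(all(is.finite(pos)), all(is.finite(k)))
    list(pos = pos, strength = k)
  }
  structure(list(attractors = as_mat(attractors), repellers = as_mat(repellers),
                 sigma_f = sigma_f, force_scale = force_scale, dt = dt,
                 damping = damping,
                 initial_position = as.numeric(initial_position),
                 boundary = boundary),
            class = "hhvg_env_config")
}

#' Field force exerted by all attractors and repellers
#'
#' @param position length-2 position, or an n x 2 matrix of positions.
#' @param config an [env_config()].
#' @return acceleration contribution; same shape as `position`.
#' @export
field_force <- function(position, config) {
  vec_in <- is.null(dim(position))
  P <- if (vec_in) matrix(position, 1, 2) else position
  if (any(!is.finite(P))) stop("non-finite position: corrupted state")
  FF <- matrix(0, nrow(P), 2)
  add <- function(FF, src, sign) {
    if (length(src$strength) == 0) return(FF)
    for (i in seq_along(src$strength)) {
      d1 <- src$pos[i, 1] - P[, 1]
      d2 <- src$pos[i, 2] - P[, 2]
      r2 <- d1 * d1 + d2 * d2
      coef <- sign * src$strength[i] *
        exp(-r2 / (2 * config$sigma_f^2)) / config$sigma_f
      FF[, 1] <- FF[, 1] + coef * d1
      FF[, 2] <- FF[, 2] + coef * d2
    }
    FF
  }
  FF <- add(FF, config$attractors, +1)
  FF <- add(FF, config$repellers, -1)
  FF <- FF * config$force_scale
  if (vec_in) FF[1, ] else FF
}

#' Initial state of a run
#' @param config an [env_config()].
#' @return numeric state (x, y, vx, vy) with zero velocities.
#' @export
env_reset <- function(config) {
  c(config$initial_position, 0, 0)
}

#' One deterministic environment step
#'
#' Total acceleration = grid acceleration of `action_index` + field force
#' (- damping * velocity).  Velocity is updated before position (explicit
#' Euler); any boundary violation clamps that axis' position to \[0, 1\] and
#' zeroes its velocity (under the default `"slide"` rule the other axis is
#' untouched).
#'
#' @param state numeric state (x, y, vx, vy).
#' @param action_index integer in \[0, 120\].
#' @param config an [env_config()].
#' @return next state.
#' @export
env_step <- function(state, action_index, config) {
  acc <- action_accel(action_index)
  drop(env_step_accel(matrix(state, 1, 4), acc, config))
}

#' Vectorised step under raw acceleration pairs
#'
#' Applies the same physics as [env_step()] to a batch of states, with the
#' commanded acceleration given directly (needed for oracle-grid generation,
#' whose action grid need not coincide with the 121-action grid).
#'
#' @param S n x 4 state matrix.
#' @param acc n x 2 commanded accelerations.
#' @param config an [env_config()].
#' @return n x 4 matrix of next states.
#' @export
env_step_accel <- function(S, acc, config) {
  if (is.null(dim(S))) S <- matrix(S, 1, 4)
  if (is.null(dim(acc))) acc <- matrix(acc, nrow(S), 2, byrow = TRUE)
  if (any(!is.finite(S))) stop("non-finite state: corrupted state")
  FF <- field_force(S[, 1:2, drop = FALSE], config)
  if (is.null(dim(FF))) FF <- matrix(FF, 1, 2)
  ax <- acc[, 1] + FF[, 1] - config$damping * S[, 3]
  ay <- acc[, 2] + FF[, 2] - config$damping * S[, 4]
  vx <- S[, 3] + ax * config$dt
  vy <- S[, 4] + ay * config$dt
  x <- S[, 1] + vx * config$dt
  y <- S[, 2] + vy * config$dt
  hit_x <- x < 0 | x > 1
  hit_y <- y < 0 | y > 1
  x <- pmin(pmax(x, 0), 1)
  y <- pmin(pmax(y, 0), 1)
  if (config$boundary == "slide") {
    vx[hit_x] <- 0
    vy[hit_y] <- 0
  } else {
    hit <- hit_x | hit_y
    vx[hit] <- 0
    vy[hit] <- 0
  }
  out <- cbind(x, y, vx, vy)
  dimnames(out) <- NULL
  out
}

#' Roll out a policy in the environment
#'
#' @param config an [env_config()].
#' @param steps number of steps.
#' @param policy `"random"` for uniform action selection, or a function
#'   `(state, t) -> action index` (t is 0-based).
#' @param seed optional seed for the random policy.
#' @return list with `states` ((steps + 1) x 4 matrix, first row the reset
#'   state) and `actions` (length `steps`, 0-based indices).
#' @export
env_rollout <- function(config, steps, policy = "random", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  random <- identical(policy, "random")
  S <- matrix(NA_real_, steps + 1, 4)
  a <- integer(steps)
  s <- env_reset(config)
  S[1, ] <- s
  if (steps > 0) {
    if (random) a <- sample.int(N_ACTIONS, steps, replace = TRUE) - 1L
    for (t in seq_len(steps)) {
      if (!random) a[t] <- policy(s, t - 1L)
      s <- env_step(s, a[t], config)
      S[t + 1, ] <- s
    }
  }
  list(states = S, actions = a)
}

#' Read / write environment configuration as YAML
#' @param path file path.
#' @param config an [env_config()].
#' @return [env_config()] for the reader; invisible path for the writer.
#' @export
read_env_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(env_config, y)
}

#' @rdname read_env_config
#' @export
write_env_config <- function(config, path) {
  y <- list(attractors = lapply(seq_along(config$attractors$strength), function(i)
              list(pos = as.numeric(config$attractors$pos[i, ]),
                   strength = config$attractors$strength[i])),
            repellers = lapply(seq_along(config$repellers$strength), function(i)
              list(pos = as.numeric(config$repellers$pos[i, ]),
                   strength = config$repellers$strength[i])),
            sigma_f = config$sigma_f, force_scale = config$force_scale,
            dt = config$dt, damping = config$damping,
            initial_position = config$initial_position,
            boundary = config$boundary)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Emits one row per step: `t`, `x`, `y`, `vx`, `vy`, `action_index`
#' (the action taken *from* that state; NA on the terminal row).
#' @param rollout result of [env_rollout()].
#' @param path output file.
#' @export
write_trajectory <- function(rollout, path) {
  n <- nrow(rollout$states)
  df <- data.frame(t = 0:(n - 1),
                   x = rollout$states[, 1], y = rollout$states[, 2],
                   vx = rollout$states[, 3], vy = rollout$states[, 4],
                   action_index = c(rollout$actions, NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
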