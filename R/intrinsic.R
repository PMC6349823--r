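# The four intrinsic-reward constructions of the ablation ladder:
#   * devaluation progress   (C/B)  — before-minus-after KL across one
#                                     meta-model update (heterostatic drive);
#   * learning progress      (C/PE) — before-minus-after forward-model MSE;
#   * replayed reward samples (PG/IRS) — time-synchronised draws from a
#                                     C/B reward database;
#   * Gaussian surrogate      (PG/GR) — N(0, 0.01^2), time-invariant.

#' Devaluation progress: the boredom-derived intrinsic reward
#'
#' `R(a, s) = L_mm(psi_before) - L_mm(psi_after)` evaluated on the same
#' transition context, where `L_mm` is the KL devaluation objective.  A
#' genuine devaluation step makes the reward positive; no gradient flows
#' through this quantity into psi when it is used as a policy/value target.
#'
#' @param fm a [forward_model()] (theta, fixed).
#' @param mm_before,mm_after meta-model parameters immediately before/after
#'   one devaluation update.
#' @param s length-4 state (or n x 4 matrix).
#' @param a length-2 acceleration (or n x 2 matrix).
#' @return numeric reward(s) in nats (may be negative).
#' @export
devaluation_progress <- function(fm, mm_before, mm_after, s, a) {
  S <- if (is.null(dim(s))) matrix(s, 1, 4) else s
  Acc <- if (is.null(dim(a))) matrix(a, 1, 2) else a
  fmout <- .fm_predict_batch(fm, S, Acc)
  s2 <- fm$sigma_s^2
  before <- .kl_pairs(fmout, .mm_outputs(mm_before, S), s2)$kl
  after <- .kl_pairs(fmout, .mm_outputs(mm_after, S), s2)$kl
  before - after
}

#' Learning progress: the prediction-error intrinsic reward
#'
#' `R = L_fm(theta_before) - L_fm(theta_after)` with
#' `L_fm = ||s' - f(a, s)||^2`; the C/PE baseline's reward.  Shares the
#' before-minus-after structure of [devaluation_progress()] with squared
#' error in place of KL.
#'
#' @param fm_before,fm_after forward models around one update.
#' @param s,a,s2 transition (vectors, or row-matched matrices).
#' @return numeric reward(s).
#' @export
learning_progress <- function(fm_before, fm_after, s, a, s2) {
  S <- if (is.null(dim(s))) matrix(s, 1, 4) else s
  Acc <- if (is.null(dim(a))) matrix(a, 1, 2) else a
  S2 <- if (is.null(dim(s2))) matrix(s2, 1, 4) else s2
  e_before <- rowSums((S2 - .fm_predict_batch(fm_before, S, Acc)$mean)^2)
  e_after <- rowSums((S2 - .fm_predict_batch(fm_after, S, Acc)$mean)^2)
  e_before - e_after
}

# ---- reward database --------------------------------------------------------

#' Create an empty intrinsic-reward database
#'
#' Stores reward samples keyed by the environment time step at which they
#' were generated, so that replay can be temporally synchronised.
#' @return object of class `hhvg_reward_db`.
#' @export
reward_db <- function() {
  structure(list(t = integer(0), value = numeric(0)), class = "hhvg_reward_db")
}

#' Append reward samples recorded at one time step
#' @param db a [reward_db()].
#' @param t environment time step (0-based).
#' @param values numeric reward samples generated at `t`.
#' @return updated database.
#' @export
reward_db_add <- function(db, t, values) {
  stopifnot(inherits(db, "hhvg_reward_db"), length(t) == 1, t >= 0)
  db$t <- c(db$t, rep.int(as.integer(t), length(values)))
  db$value <- c(db$value, as.numeric(values))
  db
}

#' Replay intrinsic rewards in a temporally synchronised manner
#'
#' Draws uniformly among the records labelled with time step `t`.  If `t`
#' carries no record (runs of different lengths), the nearest labelled time
#' step is used instead, which preserves the time-synchrony intent.
#'
#' @param db a populated [reward_db()].
#' @param t query time step.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
replay_reward <- function(db, t, n = 1) {
  if (length(db$value) == 0)
    stop("reward database is empty: run the C/B variant first")
  idx <- which(db$t == t)
  if (length(idx) == 0) {
    tn <- db$t[which.min(abs(db$t - t))]
    idx <- which(db$t == tn)
  }
  db$value[idx[sample.int(length(idx), n, replace = TRUE)]]
}

#' Gaussian surrogate reward
#'
#' Time-invariant draws from `N(0, sd^2)`; the zero mean encodes equilibrium
#' devaluation progress and the default spread matches the empirical
#' standard deviation of the reward database (0.01).
#'
#' @param n number of draws.
#' @param sd standard deviation (default 0.01).
#' @return numeric vector of length `n`.
#' @export
surrogate_reward <- function(n = 1, sd = 0.01) {
  stats::rnorm(n, 0, sd)
}

#' Write / read a reward database as a two-column CSV (t, value)
#' @param db a [reward_db()].
#' @param path file path.
#' @return the database (reader) or invisible path (writer).
#' @export
write_reward_db <- function(db, path) {
  utils::write.csv(data.frame(t = db$t, value = db$value), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_reward_db
#' @export
read_reward_db <- function(path) {
  df <- utils::read.csv(path)
  db <- reward_db()
  db$t <- as.integer(df$t)
  db$value <- as.numeric(df$value)
  db
}
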