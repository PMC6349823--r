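# Oracle grid dataset: exhaustive, unbiased sampling of the state-action
# space through the physics simulator, used to train the supervised Oracle
# forward model and to benchmark every agent variant on a common
# validation split.

#' Oracle grid specification
#'
#' The full-scale grid is 49 x 49 positions, 11 x 11 velocities and the
#' 11 x 11 action grid (49^2 * 11^4 = 35,153,041 records); tests and
#' desk-scale experiments use reduced grids.  Velocity bounds default to
#' \[-2, 2\] per axis, matching the action-grid magnitude scale.
#'
#' @param n_pos positions per axis.
#' @param n_vel velocity levels per axis.
#' @param n_act acceleration levels per axis (evenly spaced on \[-2, 2\]).
#' @param vel_range velocity range per axis.
#' @return object of class `hhvg_grid_spec`.
#' @export
oracle_grid_spec <- function(n_pos = 49, n_vel = 11, n_act = 11,
                             vel_range = c(-2, 2)) {
  structure(list(n_pos = as.integer(n_pos), n_vel = as.integer(n_vel),
                 n_act = as.integer(n_act), vel_range = as.numeric(vel_range)),
            class = "hhvg_grid_spec")
}

#' Total number of grid entries
#' @param spec an [oracle_grid_spec()].
#' @export
grid_size <- function(spec) {
  as.numeric(spec$n_pos)^2 * as.numeric(spec$n_vel)^2 * as.numeric(spec$n_act)^2
}

#' Generate the oracle transition dataset
#'
#' Every state-action grid point is passed through the physics simulator to
#' evaluate the next state; the dataset therefore contains regions (e.g.
#' repeller cores) that interactive agents can essentially never reach.
#'
#' @param spec an [oracle_grid_spec()].
#' @param env_cfg an [env_config()].
#' @return list of matrices `S` (n x 4), `Acc` (n x 2 accelerations), `S2`.
#' @export
generate_oracle_dataset <- function(spec, env_cfg) {
  pos <- seq(0, 1, length.out = spec$n_pos)
  vel <- seq(spec$vel_range[1], spec$vel_range[2], length.out = spec$n_vel)
  act <- seq(-2, 2, length.out = spec$n_act)
  g <- expand.grid(x = pos, y = pos, vx = vel, vy = vel, ax = act, ay = act,
                   KEEP.OUT.ATTRS = FALSE)
  S <- as.matrix(g[, c("x", "y", "vx", "vy")])
  Acc <- as.matrix(g[, c("ax", "ay")])
  dimnames(S) <- NULL
  dimnames(Acc) <- NULL
  S2 <- env_step_accel(S, Acc, env_cfg)
  list(S = S, Acc = Acc, S2 = S2)
}

#' Split a dataset into train / test / validation index sets
#'
#' Disjoint index sets sampled without replacement in the stated
#' proportions (0.8 / 0.16 / 0.04 by default).
#'
#' @param n number of records (or a dataset list with matrix `S`).
#' @param ratios length-3 proportions summing to at most 1.
#' @param seed reproducible sampling.
#' @return list of integer vectors `train`, `test`, `validation`.
#' @export
split_dataset <- function(n, ratios = c(0.8, 0.16, 0.04), seed = 1) {
  if (is.list(n)) n <- nrow(n$S)
  stopifnot(length(ratios) == 3, all(ratios > 0), sum(ratios) <= 1 + 1e-12)
  n_tr <- round(ratios[1] * n)
  n_te <- round(ratios[2] * n)
  n_va <- min(round(ratios[3] * n), n - n_tr - n_te)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  list(train = perm[seq_len(n_tr)],
       test = perm[n_tr + seq_len(n_te)],
       validation = perm[n_tr + n_te + seq_len(n_va)])
}

#' Train the Oracle forward model on the grid dataset
#'
#' Supervised MSE training on the train split (one Adam step on one sampled
#' batch per epoch), with the plateau learning-rate rule monitoring the
#' test-split error.
#'
#' @param dataset from [generate_oracle_dataset()].
#' @param split from [split_dataset()].
#' @param cfg an [run_config()] (`T_post` is the epoch count here when
#'   `epochs` is NULL).
#' @param epochs number of training epochs (default `cfg$T_post`).
#' @param fm optional pre-initialised [forward_model()]; by default one is
#'   created from `cfg` with the shared component seed.
#' @param test_subsample cap on test rows used for the monitored error.
#' @return list with `fm`, `test_losses`, `lr_trace`, `scheduler`.
#' @export
train_oracle <- function(dataset, split, cfg, epochs = NULL, fm = NULL,
                         test_subsample = 2000L) {
  if (is.null(epochs)) epochs <- cfg$T_post
  set.seed(as.integer(cfg$seed) + 99L)
  if (is.null(fm))
    fm <- forward_model(cfg$width, cfg$depth_fm, cfg$sigma_s, cfg$o_dim,
                        seed = as.integer(cfg$seed) + 11L)
  opt <- adam_init(fm$net$par)
  sched <- plateau_scheduler(cfg$lr_model, cfg$plateau_patience,
                             cfg$plateau_factor)
  te <- split$test
  if (length(te) > test_subsample) te <- sample(te, test_subsample)
  test_losses <- numeric(epochs)
  lr_trace <- numeric(epochs)
  if (epochs > 0) for (e in seq_len(epochs)) {
    idx <- split$train[sample.int(length(split$train),
                                  min(cfg$batch, length(split$train)))]
    up <- .fm_update(fm, opt, dataset$S[idx, , drop = FALSE],
                     dataset$Acc[idx, , drop = FALSE],
                     dataset$S2[idx, , drop = FALSE], sched$lr)
    fm <- up$fm
    opt <- up$opt
    pr <- .fm_predict_batch(fm, dataset$S[te, , drop = FALSE],
                            dataset$Acc[te, , drop = FALSE])
    test_losses[e] <- mean(rowSums((dataset$S2[te, , drop = FALSE] - pr$mean)^2))
    sched <- plateau_update(sched, test_losses[e])
    lr_trace[e] <- sched$lr
  }
  list(fm = fm, test_losses = test_losses, lr_trace = lr_trace,
       scheduler = sched)
}

#' Maximum pairwise Euclidean distance between rows
#'
#' Exact chunked O(n^2) computation; suitable for the validation-split
#' sizes used here.
#' @param X numeric matrix.
#' @param chunk rows per block.
#' @return scalar diameter of the point set.
#' @export
max_pairwise_distance <- function(X, chunk = 2000L) {
  n <- nrow(X)
  if (n < 2) stop("need at least two points")
  sq <- rowSums(X * X)
  best <- 0
  for (i0 in seq(1, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, n)
    G <- X[ii, , drop = FALSE] %*% t(X)
    D2 <- outer(sq[ii], rep(0, n), "+") + matrix(sq, length(ii), n,
                                                 byrow = TRUE) - 2 * G
    best <- max(best, max(D2))
  }
  sqrt(max(best, 0))
}

#' Benchmark error percentage of a forward model
#'
#' `100 * RMSE(s', f(a, s)) / max_{i,j} ||D_i - D_j||`, the percent ratio
#' between the root-mean-squared prediction error and the maximum pairwise
#' Euclidean distance among the validation next states.
#'
#' @param fm a [forward_model()] (or an agent holding one).
#' @param dataset oracle dataset.
#' @param idx validation index set.
#' @param max_dist optionally precomputed denominator (computed once per
#'   split and shared across variants).
#' @return list with `percent`, `mse`, `rmse`, `max_dist`.
#' @export
error_percentage <- function(fm, dataset, idx, max_dist = NULL) {
  if (inherits(fm, "hhvg_agent")) fm <- fm$fm
  if (length(idx) == 0) stop("empty validation set")
  S <- dataset$S[idx, , drop = FALSE]
  Acc <- dataset$Acc[idx, , drop = FALSE]
  S2 <- dataset$S2[idx, , drop = FALSE]
  pr <- .fm_predict_batch(fm, S, Acc)
  mse <- mean(rowSums((S2 - pr$mean)^2))
  if (is.null(max_dist)) max_dist <- max_pairwise_distance(S2)
  list(percent = 100 * sqrt(mse) / max_dist, mse = mse, rmse = sqrt(mse),
       max_dist = max_dist)
}
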