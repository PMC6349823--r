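# Behavioural metrics (Coverage Rate, Coverage Entropy on a 50 x 50
# positional grid), the mutual-information / KL decomposition diagnostic of
# the optimised policy objective, and the Mann-Whitney comparison harness.

COVERAGE_GRID <- 50L
N_CELLS <- COVERAGE_GRID^2  # 2500

#' Map positions to 50 x 50 grid cell indices
#'
#' Half-open cells `[i/50, (i+1)/50)` with the top edge closed (positions
#' exactly 1 map to the last cell).
#' @param positions n x 2 matrix of positions in \[0, 1\]^2.
#' @return integer cell ids in 1..2500.
#' @export
coverage_cells <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, 1, 2)
  if (any(positions < 0 | positions > 1))
    stop("positions must lie in the unit square")
  ix <- pmin(floor(positions[, 1] * COVERAGE_GRID), COVERAGE_GRID - 1L)
  iy <- pmin(floor(positions[, 2] * COVERAGE_GRID), COVERAGE_GRID - 1L)
  as.integer(iy * COVERAGE_GRID + ix + 1L)
}

#' Coverage Rate series
#'
#' `CR(t)` = proportion of the 2500 grid cells visited up to and including
#' step `t`; non-decreasing, starting at 1/2500 for the initial position.
#' @param positions trajectory positions (n x 2 matrix, first row = start).
#' @return numeric CR series of length n.
#' @export
coverage_rate <- function(positions) {
  cells <- coverage_cells(positions)
  cumsum(!duplicated(cells)) / N_CELLS
}

#' Coverage Entropy series
#'
#' The visit counter starts uniform (one phantom count per cell, so
#' `CE(0) = ln 2500`, the maximum); each visited position increments its
#' cell and the entropy of the normalised counter is reported per step.
#' @param positions trajectory positions (n x 2).
#' @return numeric CE series of length n (nats); `CE[1]` reflects the
#'   counter after the first position has been counted.
#' @export
coverage_entropy <- function(positions) {
  cells <- coverage_cells(positions)
  n <- length(cells)
  counts <- rep.int(1L, N_CELLS)
  total <- N_CELLS
  # H = log(total) - S/total with S = sum c*log(c); track S incrementally.
  S <- 0  # sum of 1*log(1) over all cells
  out <- numeric(n)
  for (i in seq_len(n)) {
    cc <- cells[i]
    c0 <- counts[cc]
    S <- S + (c0 + 1) * log(c0 + 1) - c0 * log(c0)
    counts[cc] <- c0 + 1L
    total <- total + 1
    out[i] <- log(total) - S / total
  }
  out
}

#' Maximum coverage entropy (uniform counter)
#' @return `ln 2500` nats.
#' @export
max_coverage_entropy <- function() log(N_CELLS)

#' Mutual-information / KL decomposition of the policy-marginal objective
#'
#' At a frozen state, the policy-averaged KL from the forward model to the
#' meta-model decomposes exactly as
#' `E_a KL(P_a || Q) = I(S':A | S = s) + KL(P(.|s) || Q)`, where
#' `P(.|s) = sum_a pi_a P_a` is the 121-component Gaussian-mixture marginal.
#' The left-hand side is computed in closed form; the mixture terms are
#' Monte-Carlo estimates over common samples, so the identity holds up to
#' the reported standard error.
#'
#' @param s length-4 state.
#' @param fm,mm,pp frozen models.
#' @param n_samples Monte-Carlo sample count.
#' @return list with `lhs`, `mi_term`, `kl_term`, `se` (standard error of
#'   `mi_term + kl_term`), and `gap = lhs - (mi_term + kl_term)`.
#' @export
mi_kl_decomposition <- function(s, fm, mm, pp, n_samples = 1e5) {
  p <- policy_distribution(pp, s)
  hd <- .fm_heads(fm, matrix(s, 1, 4))
  jac <- .jac_row(hd, 1)
  q <- meta_predict(mm, s)
  sigma2 <- fm$sigma_s^2
  ka <- .kl_actions(jac, s, sigma2, list(mu = q$mean, d = q$d, u = q$u))
  lhs <- sum(p * ka$kl)
  acts <- action_grid()
  # component covariance cholesky factors and log-dets
  n_a <- nrow(acts)
  Ls <- vector("list", n_a)
  logdets <- numeric(n_a)
  for (a in seq_len(n_a)) {
    J <- jac$A + acts[a, 1] * jac$B1 + acts[a, 2] * jac$B2
    Sp <- sigma2 * tcrossprod(J) + 1e-12 * diag(4)
    R <- chol(Sp)
    Ls[[a]] <- R
    logdets[a] <- 2 * sum(log(diag(R)))
  }
  comp <- sample.int(n_a, n_samples, replace = TRUE, prob = p)
  Z <- matrix(stats::rnorm(4 * n_samples), n_samples, 4)
  X <- ka$mean[comp, , drop = FALSE]
  for (a in unique(comp)) {
    ii <- which(comp == a)
    X[ii, ] <- X[ii, ] + Z[ii, , drop = FALSE] %*% Ls[[a]]
  }
  # log density of every sample under every mixture component
  logden <- matrix(NA_real_, n_samples, n_a)
  for (a in seq_len(n_a)) {
    Dlt <- X - matrix(ka$mean[a, ], n_samples, 4, byrow = TRUE)
    W <- backsolve(Ls[[a]], t(Dlt), transpose = TRUE)
    logden[, a] <- -0.5 * (4 * log(2 * pi) + logdets[a] + colSums(W * W))
  }
  lw <- sweep(logden, 2, log(pmax(p, 1e-300)), "+")
  mx <- apply(lw, 1, max)
  log_mix <- mx + log(rowSums(exp(lw - mx)))
  log_comp <- logden[cbind(seq_len(n_samples), comp)]
  Rq <- chol(q$cov + 1e-12 * diag(4))
  Dq <- X - matrix(q$mean, n_samples, 4, byrow = TRUE)
  Wq <- backsolve(Rq, t(Dq), transpose = TRUE)
  log_q <- -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(Rq))) + colSums(Wq * Wq))
  mi_i <- log_comp - log_mix
  kl_i <- log_mix - log_q
  tot_i <- mi_i + kl_i
  list(lhs = lhs,
       mi_term = mean(mi_i),
       kl_term = mean(kl_i),
       se = stats::sd(tot_i) / sqrt(n_samples),
       gap = lhs - mean(tot_i))
}

#' Mann-Whitney comparison of two variants' terminal scores
#'
#' One-sided rank-sum test of `a < b` (a stochastically smaller), with
#' midranks for ties and a Bonferroni-corrected significance level for the
#' two planned comparisons (alpha = 0.025).
#'
#' @param scores_a,scores_b numeric samples (e.g. terminal validation
#'   losses of two variants across runs).
#' @param alpha corrected significance level.
#' @return list with `U`, `p_value`, `alpha`, `significant`.
#' @export
compare_runs <- function(scores_a, scores_b, alpha = 0.025) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("need at least two scores per group")
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            alternative = "less"))
  list(U = unname(wt$statistic), p_value = wt$p.value, alpha = alpha,
       significant = wt$p.value < alpha)
}
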