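# Probabilistic belief models over the next state.
#
# Forward model  P(S'|a, s; theta) = N(f(a, s), J Sigma J')
#   with locally linear (bilinear) mean dynamics
#   f(a, s) = A s + (sum_i a_i B_i) s + C a + o,   J = A + sum_i a_i B_i,
#   where A (4x4), B (2x4x4), C (4x2), o are heads of an MLP trunk driven by
#   the state, and Sigma = sigma_s^2 I is a fixed base state covariance.
#
# Meta-model  Q(S'|s; psi) = N(mu', H D H')
#   with D = diag(d), d > 0 via Softplus, and H the Householder reflection
#   built from a learned vector u.  Fitting Q to the forward model's
#   predictions (in KL) realises outcome devaluation ("boredom").

#' Gaussian belief over the next state
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix (symmetric PSD).
#' @return object of class `hhvg_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  stopifnot(is.matrix(cov), nrow(cov) == length(mean), ncol(cov) == length(mean))
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  structure(list(mean = mean, cov = (cov + t(cov)) / 2), class = "hhvg_belief")
}

#' Draw samples from a Gaussian belief
#' @param belief an [gaussian_belief()].
#' @param n number of draws.
#' @return n x k matrix.
#' @export
sample_belief <- function(belief, n) {
  k <- length(belief$mean)
  L <- t(chol(belief$cov + 1e-12 * diag(k)))
  Z <- matrix(stats::rnorm(n * k), k, n)
  t(L %*% Z + belief$mean)
}

# ---- forward model ----------------------------------------------------------

#' Create a bilinear-Jacobian Gaussian forward model
#'
#' The MLP trunk consumes the 4-dim state and emits four linear heads of
#' sizes 16, 32, 8 and `o_dim`, reshaped into A (4x4), B (2x4x4), C (4x2)
#' and the offset o.  With `o_dim = 1` the scalar offset is broadcast to all
#' four state coordinates; the default is a full 4-dim offset.
#'
#' @param width trunk width (full-scale configuration: 512).
#' @param depth number of ReLU trunk layers (default 4).
#' @param sigma_s base state standard deviation; the fixed state covariance
#'   is `sigma_s^2 * I` and only shapes the KL geometry in this
#'   deterministic environment.
#' @param o_dim 4 (default) or 1 (scalar broadcast offset).
#' @param seed reproducible Xavier initialisation.
#' @return object of class `hhvg_forward_model`.
#' @export
forward_model <- function(width = 512, depth = 4, sigma_s = 0.01,
                          o_dim = 4, seed = NULL) {
  stopifnot(sigma_s > 0, o_dim %in% c(1L, 4L))
  net <- mlp_init(4, width, depth,
                  heads = c(A = 16L, B = 32L, C = 8L, o = as.integer(o_dim)),
                  seed = seed)
  structure(list(net = net, sigma_s = sigma_s, o_dim = as.integer(o_dim)),
            class = "hhvg_forward_model")
}

#' Local Jacobian factors of the forward model at a state
#'
#' Returns the reshaped trunk heads: `A` (4x4), `B` (2x4x4 array, action
#' component along the first axis), `C` (4x2) and `o` (length 4).  These do
#' not depend on the action: the action enters the assembled mean exactly
#' bilinearly, so `df/da = C + (B_1 s, B_2 s)` holds identically and
#' `A + sum_i a_i B_i` is the local state Jacobian of the assembled affine
#' map (held at these factor values).
#'
#' @param fm a [forward_model()].
#' @param s length-4 state.
#' @return list with `A`, `B`, `C`, `o`.
#' @export
build_jacobians <- function(fm, s) {
  stopifnot(length(s) == 4, all(is.finite(s)))
  h <- mlp_forward(fm$net, s)$heads
  A <- matrix(h$A[1, ], 4, 4)
  B <- array(0, c(2, 4, 4))
  B[1, , ] <- matrix(h$B[1, 1:16], 4, 4)
  B[2, , ] <- matrix(h$B[1, 17:32], 4, 4)
  C <- matrix(h$C[1, ], 4, 2)
  o <- if (fm$o_dim == 1L) rep(h$o[1, 1], 4) else as.numeric(h$o[1, ])
  list(A = A, B = B, C = C, o = o)
}

#' Forward-model predictive belief
#'
#' Mean `f(a, s) = A s + (sum_i a_i B_i) s + C a + o`; covariance
#' `J Sigma J'` with `J = A + sum_i a_i B_i` and `Sigma = sigma_s^2 I`,
#' positive semi-definite by construction.
#'
#' @param fm a [forward_model()].
#' @param s length-4 state.
#' @param a length-2 acceleration pair (the continuous action).
#' @return a [gaussian_belief()].
#' @export
predict_forward <- function(fm, s, a) {
  stopifnot(length(a) == 2, all(is.finite(a)))
  jac <- build_jacobians(fm, s)
  J <- jac$A + a[1] * jac$B[1, , ] + a[2] * jac$B[2, , ]
  mu <- drop(J %*% s + jac$C %*% a) + jac$o
  gaussian_belief(mu, fm$sigma_s^2 * tcrossprod(J))
}

# Batched trunk evaluation: flat heads for n states.
# Layout: column-major vec, element (i, j) of a 4x4 at flat column (j-1)*4+i.
.fm_heads <- function(fm, S, keep_cache = FALSE) {
  out <- mlp_forward(fm$net, S, keep_cache = keep_cache)
  h <- out$heads
  o <- if (fm$o_dim == 1L) matrix(h$o[, 1], nrow(h$o), 4) else h$o
  list(A = h$A, B = h$B, C = h$C, o = o, cache = out$cache)
}

# Batched mean and flat Jacobian: S (n x 4), Acc (n x 2).
.fm_predict_batch <- function(fm, S, Acc, keep_cache = FALSE) {
  hd <- .fm_heads(fm, S, keep_cache = keep_cache)
  Jflat <- hd$A + Acc[, 1] * hd$B[, 1:16, drop = FALSE] +
                  Acc[, 2] * hd$B[, 17:32, drop = FALSE]
  mu <- matrix(0, nrow(S), 4)
  for (i in 1:4) {
    acc_i <- hd$o[, i] + hd$C[, i] * Acc[, 1] + hd$C[, 4 + i] * Acc[, 2]
    for (j in 1:4) acc_i <- acc_i + Jflat[, (j - 1) * 4 + i] * S[, j]
    mu[, i] <- acc_i
  }
  list(mean = mu, Jflat = Jflat, heads = hd)
}

# Determinants of n 4x4 matrices given as flat rows (column-major layout),
# by Laplace expansion in complementary 2x2 minors.
.det4_flat <- function(Jf) {
  M <- function(i, j) Jf[, (j - 1) * 4 + i]
  m12 <- M(1, 1) * M(2, 2) - M(2, 1) * M(1, 2)
  m13 <- M(1, 1) * M(3, 2) - M(3, 1) * M(1, 2)
  m14 <- M(1, 1) * M(4, 2) - M(4, 1) * M(1, 2)
  m23 <- M(2, 1) * M(3, 2) - M(3, 1) * M(2, 2)
  m24 <- M(2, 1) * M(4, 2) - M(4, 1) * M(2, 2)
  m34 <- M(3, 1) * M(4, 2) - M(4, 1) * M(3, 2)
  n12 <- M(1, 3) * M(2, 4) - M(2, 3) * M(1, 4)
  n13 <- M(1, 3) * M(3, 4) - M(3, 3) * M(1, 4)
  n14 <- M(1, 3) * M(4, 4) - M(4, 3) * M(1, 4)
  n23 <- M(2, 3) * M(3, 4) - M(3, 3) * M(2, 4)
  n24 <- M(2, 3) * M(4, 4) - M(4, 3) * M(2, 4)
  n34 <- M(3, 3) * M(4, 4) - M(4, 3) * M(3, 4)
  m12 * n34 - m13 * n24 + m14 * n23 + m23 * n14 - m24 * n13 + m34 * n12
}

# ---- meta-model -------------------------------------------------------------

#' Householder reflection from a vector
#'
#' `H = I - 2 u u' / ||u||^2`: symmetric, orthogonal, determinant -1,
#' invariant to rescaling of `u`.
#'
#' @param u nonzero numeric vector.
#' @return square orthogonal matrix.
#' @export
householder_orthogonal <- function(u) {
  u <- as.numeric(u)
  n2 <- sum(u * u)
  if (!is.finite(n2) || n2 <= 0) stop("Householder vector must be nonzero")
  diag(length(u)) - 2 * tcrossprod(u) / n2
}

#' Create a Householder-covariance Gaussian meta-model
#'
#' Three disjoint towers (each: `depth` ReLU layers + single-layer residual
#' connection + linear output) map the state to the predictive mean `mu'`,
#' the positive spectrum `d` (Softplus) and the Householder vector `u`;
#' the covariance is `H D H'` with `D = diag(d)`.
#'
#' @param width tower width (full-scale configuration: 512).
#' @param depth ReLU layers per tower (default 3).
#' @param seed reproducible initialisation.
#' @return object of class `hhvg_meta_model`.
#' @export
meta_model <- function(width = 512, depth = 3, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  structure(list(mu = mlp_init(4, width, depth, c(out = 4L), seed = seeds[[1]]),
                 d  = mlp_init(4, width, depth, c(out = 4L), seed = seeds[[2]]),
                 u  = mlp_init(4, width, depth, c(out = 4L), seed = seeds[[3]])),
            class = "hhvg_meta_model")
}

# Batched meta-model outputs: mu (n x 4), zd (pre-Softplus), d, u.
.mm_outputs <- function(mm, S, keep_cache = FALSE) {
  fmu <- mlp_forward(mm$mu, S, keep_cache = keep_cache)
  fd <- mlp_forward(mm$d, S, keep_cache = keep_cache)
  fu <- mlp_forward(mm$u, S, keep_cache = keep_cache)
  list(mu = fmu$heads$out, zd = fd$heads$out, d = .softplus(fd$heads$out),
       u = fu$heads$out,
       cache_mu = fmu$cache, cache_d = fd$cache, cache_u = fu$cache)
}

# Covariance H D H' from spectrum d and Householder vector u (u = 0 falls
# back to H = I inside training kernels; the public path errors instead).
.meta_cov <- function(d, u) {
  n2 <- sum(u * u)
  H <- if (n2 < 1e-30) diag(4) else diag(4) - 2 * tcrossprod(u) / n2
  list(H = H, cov = tcrossprod(sweep(H, 2, d, "*"), H))
}

#' Meta-model predictive belief at a state
#'
#' @param mm a [meta_model()].
#' @param s length-4 state.
#' @return a [gaussian_belief()] with extra fields `d`, `u`, `H`.
#' @export
meta_predict <- function(mm, s) {
  stopifnot(length(s) == 4, all(is.finite(s)))
  out <- .mm_outputs(mm, matrix(s, 1, 4))
  u <- as.numeric(out$u[1, ])
  H <- householder_orthogonal(u)
  d <- as.numeric(out$d[1, ])
  b <- gaussian_belief(as.numeric(out$mu[1, ]),
                       tcrossprod(sweep(H, 2, d, "*"), H))
  b$d <- d; b$u <- u; b$H <- H
  b
}

# ---- Kullback-Leibler machinery --------------------------------------------

#' Closed-form KL divergence between two Gaussian beliefs
#'
#' `KL(p || q) = (tr(Sq^-1 Sp) + (mq - mp)' Sq^-1 (mq - mp) - k
#'               + log|Sq| - log|Sp|) / 2`.
#'
#' @param p,q [gaussian_belief()] objects of equal dimension.
#' @param jitter added to the `q` covariance diagonal before inversion
#'   (Softplus spectra can underflow); also used as a last-resort
#'   regulariser of a numerically singular `p` covariance log-determinant.
#' @return non-negative scalar (nats); zero iff p equals q.
#' @export
gaussian_kl <- function(p, q, jitter = 1e-6) {
  k <- length(p$mean)
  stopifnot(length(q$mean) == k)
  Rq <- tryCatch(chol(q$cov + jitter * diag(k)), error = function(e) NULL)
  if (is.null(Rq))
    stop("q covariance is singular; increase the jitter")
  logdet_q <- 2 * sum(log(diag(Rq)))
  Rp <- tryCatch(chol(p$cov), error = function(e) chol(p$cov + jitter * diag(k)))
  logdet_p <- 2 * sum(log(diag(Rp)))
  Sqinv <- chol2inv(Rq)
  delta <- q$mean - p$mean
  0.5 * (sum(Sqinv * p$cov) + drop(crossprod(delta, Sqinv %*% delta)) - k +
           logdet_q - logdet_p)
}

#' Devaluation objective at one transition context
#'
#' `L_mm(psi) = KL(P(.|a, s; theta) || Q(.|s; psi))` — the homeostatic drive:
#' minimising it in psi assimilates the forward model's prediction into the
#' meta-model.
#'
#' @param fm a [forward_model()] (theta, held fixed).
#' @param mm a [meta_model()] (psi).
#' @param s length-4 state.
#' @param a length-2 acceleration pair.
#' @return scalar KL in nats.
#' @export
devaluation_objective <- function(fm, mm, s, a) {
  gaussian_kl(predict_forward(fm, s, a), meta_predict(mm, s))
}

# Per-sample KL between forward beliefs and meta beliefs, plus (optionally)
# gradients of mean KL w.r.t. the meta outputs (mu, zd, u).  fmout from
# .fm_predict_batch, mmout from .mm_outputs; sigma2 = fm$sigma_s^2.
.kl_pairs <- function(fmout, mmout, sigma2, grads = FALSE) {
  n <- nrow(fmout$mean)
  detJ <- .det4_flat(fmout$Jflat)
  logdet_p <- 4 * log(sigma2) + log(pmax(detJ * detJ, 1e-300))
  kl <- numeric(n)
  if (grads) {
    gmu <- matrix(0, n, 4); gzd <- matrix(0, n, 4); gu <- matrix(0, n, 4)
  }
  for (i in seq_len(n)) {
    J <- matrix(fmout$Jflat[i, ], 4, 4)
    Sp <- sigma2 * tcrossprod(J)
    d <- mmout$d[i, ]
    u <- mmout$u[i, ]
    n2 <- sum(u * u)
    H <- if (n2 < 1e-30) diag(4) else diag(4) - 2 * tcrossprod(u) / n2
    Hd <- sweep(H, 2, 1 / d, "*")
    Sqinv <- tcrossprod(Hd, H)                    # H D^-1 H'
    delta <- mmout$mu[i, ] - fmout$mean[i, ]
    sd_ <- drop(Sqinv %*% delta)
    kl[i] <- 0.5 * (sum(Sqinv * Sp) + sum(delta * sd_) - 4 +
                      sum(log(d)) - logdet_p[i])
    if (grads) {
      G <- 0.5 * (Sqinv - Sqinv %*% (Sp + tcrossprod(delta)) %*% Sqinv)
      gmu[i, ] <- sd_
      gd <- colSums(H * (G %*% H))
      gzd[i, ] <- gd * .sigmoid(mmout$zd[i, ])
      if (n2 >= 1e-30) {
        W <- 2 * (G %*% sweep(H, 2, d, "*"))
        gu[i, ] <- drop(-2 * ((W + t(W)) %*% u) / n2 +
                          4 * u * drop(crossprod(u, W %*% u)) / n2^2)
      }
    }
  }
  out <- list(kl = kl)
  if (grads) { out$gmu <- gmu; out$gzd <- gzd; out$gu <- gu }
  out
}

# One devaluation (meta-model) update on a batch: Adam step on psi minimising
# the batch-mean KL; theta fixed.  Returns kl_before per sample.
.mm_update <- function(mm, opts, fmout, S, lr, sigma2) {
  mo <- .mm_outputs(mm, S, keep_cache = TRUE)
  kg <- .kl_pairs(fmout, mo, sigma2, grads = TRUE)
  n <- nrow(S)
  g_mu <- mlp_backward(mm$mu, mo$cache_mu, list(out = kg$gmu / n))
  g_d <- mlp_backward(mm$d, mo$cache_d, list(out = kg$gzd / n))
  g_u <- mlp_backward(mm$u, mo$cache_u, list(out = kg$gu / n))
  up <- adam_step(mm$mu$par, g_mu, opts$mu, lr)
  mm$mu$par <- up$par; opts$mu <- up$opt
  up <- adam_step(mm$d$par, g_d, opts$d, lr)
  mm$d$par <- up$par; opts$d <- up$opt
  up <- adam_step(mm$u$par, g_u, opts$u, lr)
  mm$u$par <- up$par; opts$u <- up$opt
  list(mm = mm, opts = opts, kl_before = kg$kl)
}

# One forward-model update on a batch: Adam step on theta minimising the
# batch-mean squared error ||s' - f(a, s)||^2.  Returns per-sample squared
# errors before the update.
.fm_update <- function(fm, opt, S, Acc, S2, lr) {
  pr <- .fm_predict_batch(fm, S, Acc, keep_cache = TRUE)
  resid <- pr$mean - S2
  sqerr <- rowSums(resid * resid)
  n <- nrow(S)
  gf <- 2 * resid / n
  gA <- matrix(0, n, 16)
  for (j in 1:4) for (i in 1:4) gA[, (j - 1) * 4 + i] <- gf[, i] * S[, j]
  gB <- cbind(Acc[, 1] * gA, Acc[, 2] * gA)
  gC <- matrix(0, n, 8)
  for (i in 1:4) { gC[, i] <- gf[, i] * Acc[, 1]; gC[, 4 + i] <- gf[, i] * Acc[, 2] }
  go <- if (fm$o_dim == 1L) matrix(rowSums(gf), n, 1) else gf
  g <- mlp_backward(fm$net, pr$heads$cache,
                    list(A = gA, B = gB, C = gC, o = go))
  up <- adam_step(fm$net$par, g, opt, lr)
  fm$net$par <- up$par
  list(fm = fm, opt = up$opt, sqerr_before = sqerr)
}

# All-action KL sweep at a single state: kl (121), means (121 x 4) and,
# if weights w are given, gradients of sum_a w_a KL_a w.r.t. meta outputs.
# jac: list from build_jacobians-style flat heads for ONE state
# (A 4x4, B1, B2, C, o); q: list(mu, d, u, zd optional).
.kl_actions <- function(jac, s, sigma2, q, acts = action_grid(), w = NULL) {
  n_a <- nrow(acts)
  vA <- as.vector(jac$A); vB1 <- as.vector(jac$B1); vB2 <- as.vector(jac$B2)
  Jflat <- matrix(vA, n_a, 16, byrow = TRUE) +
    outer(acts[, 1], vB1) + outer(acts[, 2], vB2)
  mu <- matrix(0, n_a, 4)
  for (i in 1:4) {
    acc_i <- jac$o[i] + jac$C[i, 1] * acts[, 1] + jac$C[i, 2] * acts[, 2]
    for (j in 1:4) acc_i <- acc_i + Jflat[, (j - 1) * 4 + i] * s[j]
    mu[, i] <- acc_i
  }
  d <- q$d; u <- q$u
  n2 <- sum(u * u)
  H <- if (n2 < 1e-30) diag(4) else diag(4) - 2 * tcrossprod(u) / n2
  Sqinv <- tcrossprod(sweep(H, 2, 1 / d, "*"), H)
  logdet_q <- sum(log(d))
  arr <- array(as.vector(t(Jflat)), dim = c(4, 4, n_a))
  Jstack <- matrix(arr, 4, 4 * n_a)
  P <- Sqinv %*% Jstack
  tr_a <- colSums(matrix(colSums(P * Jstack), 4, n_a))
  Dlt <- matrix(q$mu, n_a, 4, byrow = TRUE) - mu
  quad <- rowSums((Dlt %*% Sqinv) * Dlt)
  detJ <- .det4_flat(Jflat)
  logdet_p <- 4 * log(sigma2) + log(pmax(detJ * detJ, 1e-300))
  kl <- 0.5 * (sigma2 * tr_a + quad - 4 + logdet_q - logdet_p)
  out <- list(kl = kl, mean = mu)
  if (!is.null(w)) {
    ws <- rep(w, each = 4)
    M <- sigma2 * (sweep(Jstack, 2, ws, "*") %*% t(Jstack)) +
      crossprod(Dlt * w, Dlt)
    G <- 0.5 * (sum(w) * Sqinv - Sqinv %*% M %*% Sqinv)
    out$gmu <- drop(Sqinv %*% colSums(Dlt * w))
    gd <- colSums(H * (G %*% H))
    out$gd <- gd
    if (!is.null(q$zd)) out$gzd <- gd * .sigmoid(q$zd)
    if (n2 >= 1e-30) {
      W <- 2 * (G %*% sweep(H, 2, d, "*"))
      out$gu <- drop(-2 * ((W + t(W)) %*% u) / n2 +
                       4 * u * drop(crossprod(u, W %*% u)) / n2^2)
    } else out$gu <- numeric(4)
  }
  out
}

# Flat per-state Jacobian pieces for .kl_actions from batched heads (row i).
.jac_row <- function(hd, i) {
  list(A = matrix(hd$A[i, ], 4, 4),
       B1 = matrix(hd$B[i, 1:16], 4, 4),
       B2 = matrix(hd$B[i, 17:32], 4, 4),
       C = matrix(hd$C[i, ], 4, 2),
       o = hd$o[i, ])
}
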