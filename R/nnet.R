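# Dense multilayer perceptron with a single-layer residual connection and
# named linear heads.  All networks in the package (forward model trunk,
# meta-model towers, policy, value) share this structure:
#
#   h = ReLU(W_L ... ReLU(W_1 x)) + W_res x + b_res
#   y_k = h W_k + b_k                (one linear head per named output)
#
# Parameters live in a flat named list so that optimiser state can be mapped
# over them generically.  Gradients are computed by hand (reverse mode); their
# correctness is established by finite-difference tests.

#' Create a dense MLP with ReLU hidden layers, a residual connection and
#' named linear output heads
#'
#' Weights follow Xavier (Glorot) uniform initialisation.
#'
#' @param d_in input dimension.
#' @param width hidden layer width.
#' @param depth number of hidden (ReLU) layers.
#' @param heads named integer vector of output head dimensions,
#'   e.g. `c(A = 16, B = 32, C = 8, o = 4)`.
#' @param seed optional integer seed; when given, initialisation is
#'   reproducible and the global RNG state is restored on exit.
#' @return an object of class `hhvg_mlp`.
#' @export
mlp_init <- function(d_in, width, depth, heads, seed = NULL) {
  stopifnot(d_in >= 1, width >= 1, depth >= 1, length(heads) >= 1,
            !is.null(names(heads)), all(nzchar(names(heads))))
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  par <- list()
  d_prev <- d_in
  for (l in seq_len(depth)) {
    par[[paste0("W", l)]] <- .xavier(d_prev, width)
    par[[paste0("b", l)]] <- numeric(width)
    d_prev <- width
  }
  par[["Wres"]] <- .xavier(d_in, width)
  par[["bres"]] <- numeric(width)
  for (k in names(heads)) {
    par[[paste0("W_", k)]] <- .xavier(width, heads[[k]])
    par[[paste0("b_", k)]] <- numeric(heads[[k]])
  }
  structure(list(d_in = d_in, width = width, depth = depth,
                 heads = heads, par = par),
            class = "hhvg_mlp")
}

.xavier <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Forward pass of an MLP
#'
#' @param net an `hhvg_mlp`.
#' @param X numeric matrix, one row per input (n x d_in); a bare vector is
#'   treated as a single row.
#' @param keep_cache keep intermediate activations for [mlp_backward()].
#' @return list with `heads` (named list of n x d_k matrices) and,
#'   if requested, `cache`.
#' @export
mlp_forward <- function(net, X, keep_cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == net$d_in)
  p <- net$par
  Z <- vector("list", net$depth)
  H <- vector("list", net$depth)
  h <- X
  for (l in seq_len(net$depth)) {
    z <- h %*% p[[paste0("W", l)]]
    z <- sweep(z, 2, p[[paste0("b", l)]], "+")
    Z[[l]] <- z
    h <- z * (z > 0)
    H[[l]] <- h
  }
  trunk <- h + sweep(X %*% p$Wres, 2, p$bres, "+")
  heads <- lapply(names(net$heads), function(k)
    sweep(trunk %*% p[[paste0("W_", k)]], 2, p[[paste0("b_", k)]], "+"))
  names(heads) <- names(net$heads)
  out <- list(heads = heads)
  if (keep_cache) out$cache <- list(X = X, Z = Z, H = H, trunk = trunk)
  out
}

#' Backward pass: parameter gradients from head output gradients
#'
#' `ghead` entries must already carry any loss-level scaling (e.g. 1/n for a
#' batch mean); heads absent from `ghead` contribute nothing.
#'
#' @param net an `hhvg_mlp`.
#' @param cache cache from `mlp_forward(..., keep_cache = TRUE)`.
#' @param ghead named list of gradients w.r.t. head outputs (n x d_k).
#' @return named list of gradients matching `net$par`.
#' @export
mlp_backward <- function(net, cache, ghead) {
  p <- net$par
  X <- cache$X
  n <- nrow(X)
  g <- vector("list", length(p))
  names(g) <- names(p)
  gtrunk <- matrix(0, n, net$width)
  for (k in names(ghead)) {
    stopifnot(k %in% names(net$heads))
    gh <- ghead[[k]]
    if (is.null(dim(gh))) gh <- matrix(gh, nrow = n)
    g[[paste0("W_", k)]] <- crossprod(cache$trunk, gh)
    g[[paste0("b_", k)]] <- colSums(gh)
    gtrunk <- gtrunk + tcrossprod(gh, p[[paste0("W_", k)]])
  }
  for (k in names(net$heads)) {        # heads not driven get zero gradients
    if (is.null(g[[paste0("W_", k)]])) {
      g[[paste0("W_", k)]] <- matrix(0, net$width, net$heads[[k]])
      g[[paste0("b_", k)]] <- numeric(net$heads[[k]])
    }
  }
  g$Wres <- crossprod(X, gtrunk)
  g$bres <- colSums(gtrunk)
  gh <- gtrunk
  for (l in rev(seq_len(net$depth))) {
    gz <- gh * (cache$Z[[l]] > 0)
    h_prev <- if (l == 1) X else cache$H[[l - 1]]
    g[[paste0("W", l)]] <- crossprod(h_prev, gz)
    g[[paste0("b", l)]] <- colSums(gz)
    gh <- tcrossprod(gz, p[[paste0("W", l)]])
  }
  g
}

# ---- Adam optimiser over flat parameter lists -------------------------------

#' Initialise Adam state for a parameter list
#' @param par named list of numeric arrays (e.g. `net$par`).
#' @return optimiser state.
#' @export
adam_init <- function(par) {
  zeros <- lapply(par, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam update
#'
#' @param par,grads parameter list and matching gradient list.
#' @param opt state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps usual Adam constants.
#' @return list with updated `par` and `opt`.
#' @export
adam_step <- function(par, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in names(par)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * gk
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * gk * gk
    par[[k]] <- par[[k]] - lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
  }
  list(par = par, opt = opt)
}

# Softplus and its derivative (numerically stable)
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.sigmoid <- function(x) 1 / (1 + exp(-x))
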