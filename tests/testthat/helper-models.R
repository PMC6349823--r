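# Small model fixtures and numeric utilities shared across tests.

tiny_fm <- function(width = 16, seed = 1, sigma_s = 0.01, o_dim = 4)
  forward_model(width = width, depth = 2, sigma_s = sigma_s, o_dim = o_dim,
                seed = seed)

tiny_mm <- function(width = 16, seed = 2)
  meta_model(width = width, depth = 2, seed = seed)

tiny_pp <- function(width = 16, seed = 3)
  policy_network(width = width, depth = 2, seed = seed)

tiny_vp <- function(width = 16, seed = 4)
  value_network(width = width, depth = 2, seed = seed)

rand_state <- function(n = 1) {
  S <- cbind(runif(n), runif(n), rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  if (n == 1) drop(S) else S
}

rand_belief <- function(dim = 4, scale = 0.5) {
  M <- matrix(rnorm(dim * dim, sd = scale), dim, dim)
  gaussian_belief(rnorm(dim), crossprod(M) + 0.05 * diag(dim))
}

# Set every parameter of an MLP to zero (so heads emit their biases).
zero_net <- function(net) {
  net$par <- lapply(net$par, function(x) x * 0)
  net
}

# Results of the scaled ablation experiment are computed once and shared by
# the acceptance tests that need them.
.ablation_cache <- new.env(parent = emptyenv())
ablation_results <- function() {
  if (is.null(.ablation_cache$res))
    .ablation_cache$res <- ablation_experiment(seeds = 1:3)
  .ablation_cache$res
}
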