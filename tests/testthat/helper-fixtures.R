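# Small builders shared across tests.

tiny_config <- function(...) {
  model_config(h1 = 16, h2 = 8, d_z = 4, h3 = 8, ...)
}

tiny_params <- function(D = 10, n_cov = 2, K = 3, seed = 7) {
  init_params(D, n_cov, K, model_config(h1 = 7, h2 = 5, d_z = 3, h3 = 4),
              seed = seed)
}

random_batch <- function(n, D, seed = 1) {
  set.seed(seed)
  matrix(abs(rnorm(n * D)), n, D)
}

# single-block dataset with two covariate levels, for trainer tests
toy_dataset <- function(n = 60, D = 12, seed = 1) {
  set.seed(seed)
  lay <- block_layout(rna = paste0("g", seq_len(D)))
  X <- matrix(abs(rnorm(n * D)), n, D)
  labels <- factor(sample(c("a", "b"), n, replace = TRUE))
  stacked_dataset(X, lay, covariate = rep(1:2, length.out = n), labels = labels)
}

# central finite difference of a scalar function of one parameter entry
fd_grad <- function(params, name, i, f, h = 1e-6) {
  pp <- params; pp[[name]][i] <- pp[[name]][i] + h
  pm <- params; pm[[name]][i] <- pm[[name]][i] - h
  (f(pp) - f(pm)) / (2 * h)
}
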