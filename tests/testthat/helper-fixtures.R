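## Small fixtures shared across test files; everything is generated in code.

## tiny contiguous structure: `sizes` genes per cluster
toy_structure <- function(sizes = c(2L, 2L), n0 = 2L) {
  omics_structure(rep(seq_along(sizes), times = sizes), n0 = n0)
}

## random logistic screening instance on a small tri-level design
rand_instance <- function(seed, n = 60L, sizes = c(3L, 3L, 2L), n0 = 2L,
                          pis = c(0.5, 0.3, 0.3, 0.1), n_signal = 2L,
                          effect = 1.5) {
  set.seed(seed)
  st <- toy_structure(sizes, n0)
  S <- as.matrix(build_covariance(st, pis))
  X <- matrix(rnorm(n * st$p), n, st$p) %*% chol(S)
  beta <- numeric(st$p)
  signal <- sample(st$G, n_signal)
  for (g in signal) {
    cols <- st$columns_of_gene[[g]]
    beta[cols] <- rnorm(n0, 0, effect)
  }
  y <- rbinom(n, 1, plogis(as.numeric(X %*% beta)))
  list(X = X, y = y, structure = st, beta = beta, signal = sort(signal))
}

## dense evaluation of the quadratic surrogate g(omega | beta) given the
## block weights; independent of the package's block-wise code paths
dense_surrogate <- function(X, y, beta, beta0, W, u, omega) {
  st <- W$structure
  Wd <- matrix(0, st$p, st$p)
  for (g in seq_len(st$G)) {
    cols <- st$columns_of_gene[[g]]
    Wd[cols, cols] <- W$blocks[[g]] * W$scale[g]
  }
  d <- omega - beta
  loglik(X, y, beta, beta0) + sum(d * gradient(X, y, beta, beta0)) -
    (u / 2) * as.numeric(t(d) %*% Wd %*% d)
}
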