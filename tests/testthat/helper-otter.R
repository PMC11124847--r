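# Shared fixtures and independent oracles, built in code at test time.

# fast acquisition settings for unit tests (the package defaults, 512 points,
# are exercised in the acceptance tests)
acq_fast <- function(noise_sd = 0.01, n_points = 128) {
  acquisition_config(n_points = n_points, noise_sd = noise_sd)
}

# Independent layered-superposition oracle for a depth-dependent absorption
# coefficient: direct trapezoid quadrature of the one-dimensional emission
# integral S(t) = (A/beta(0)) * int beta(z) exp(-int_0^z beta) *
# exp(-z^2 / 4 D t) / sqrt(pi D t) dz. Shares no code with the closed-form
# signal models.
quad_oracle_signal <- function(t, A, beta_fun, D, n_z = 20001) {
  beta0 <- beta_fun(0)
  vapply(t, function(tt) {
    if (tt == 0) return(A)
    L <- sqrt(D * tt)
    zmax <- 12 * L + 12 / beta0
    z <- seq(0, zmax, length.out = n_z)
    b <- pmax(beta_fun(z), 0)
    cumb <- cumsum(c(0, (b[-1] + b[-length(b)]) / 2 * diff(z)))
    f <- b * exp(-cumb) * exp(-z^2 / (4 * D * tt)) / sqrt(pi * D * tt)
    A / beta0 * sum((f[-1] + f[-length(f)]) / 2 * diff(z))
  }, numeric(1))
}

# brute-force leave-one-out 1-nearest-neighbour accuracy on raw rows
loo_1nn_accuracy <- function(X, y) {
  n <- nrow(X)
  hits <- vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(X[-i, , drop = FALSE], 2, X[i, ])^2))
    as.character(y[-i][which.min(d)]) == as.character(y[i])
  }, logical(1))
  mean(hits)
}

# brute-force PCA scores via eigendecomposition of the centred covariance
brute_pca_scores <- function(X, k = 2) {
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  Xc %*% eg$vectors[, seq_len(k), drop = FALSE]
}
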