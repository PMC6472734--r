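# Shared fixtures and independent oracles for the test suite.

# small study-shaped study (full design structure, few edges)
tiny_study <- function(n_edges = 80, seed = 1, params = reference_scale_params(),
                       model = "different") {
  generate_study(n_edges = n_edges, params = params, model = model,
                 seed = seed)
}

# independent equality-constrained ridge oracle: null-space elimination
# (parameterize w = Z v with Z a basis of null(C), solve the reduced
# regularized normal equations) -- a different route than the KKT system
# used by the implementation
qp_nullspace_oracle <- function(X, C, lambda, penalty, y) {
  Z <- MASS::Null(t(C))
  H <- t(Z) %*% (crossprod(X) + diag(lambda * penalty, ncol(X))) %*% Z
  v <- solve(H, t(Z) %*% crossprod(X, y))
  drop(Z %*% v)
}

# random small constrained-ridge instance (identifiable on the null space)
random_qp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:30, 1)
  p <- sample(4:10, 1)
  X <- matrix(rnorm(n * p), n, p)
  q <- sample(1:2, 1)
  C <- matrix(rnorm(q * p), q, p)
  penalty <- rep(1, p)
  penalty[sample(p, 1)] <- 0
  list(X = X, C = C, penalty = penalty,
       lambda = runif(1, 0.01, 5), y = rnorm(n))
}

# sinusoid amplitude via least squares on a sin/cos basis
sine_amplitude <- function(x, freq_hz, tr) {
  t <- (seq_along(x) - 1) * tr
  fit <- lm(x ~ sin(2 * pi * freq_hz * t) + cos(2 * pi * freq_hz * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

expect_block_cor_above <- function(est, truth, threshold) {
  shared <- intersect(rownames(est), rownames(truth))
  cors <- vapply(shared, function(l) cor(est[l, ], truth[l, ]), numeric(1))
  expect_gt(mean(cors), threshold)
}
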