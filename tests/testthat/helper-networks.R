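# Shared fixtures, all built in code.

# Generic matrix-exponential oracle, independent of propagator().
expm_oracle <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# Random matrix rescaled to a prescribed spectral abscissa (< 1 => stable).
random_stable_matrix <- function(N, abscissa = 0.5, scale = 1) {
  J <- matrix(rnorm(N * N, sd = scale / sqrt(N)), N, N)
  sa <- max(Re(eigen(J, only.values = TRUE)$values))
  J - diag(max(0, sa - abscissa), N)
}

# Exactly orthonormal u, v in dimension N (deterministic given the RNG state).
orthonormal_pair <- function(N) {
  x1 <- rnorm(N); x2 <- rnorm(N)
  u <- x1 / sqrt(sum(x1^2))
  w <- x2 - sum(u * x2) * u
  list(u = u, v = w / sqrt(sum(w^2)))
}

# Unit-rank network J = Delta u v^T from an exact pair with correlation rho.
rank1_net <- function(N, Delta, rho = 0, seed = NULL) {
  pr <- structure_pair(rho, N, seed = seed, mode = "exact")
  list(net = network_model(Delta * tcrossprod(pr$u, pr$v)),
       u = pr$u, v = pr$v)
}

# sigma1 of the true propagator via the generic oracle.
sigma1_oracle <- function(J, t) {
  svd(expm_oracle(t * (J - diag(nrow(J)))), nu = 0, nv = 0)$d[1]
}
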