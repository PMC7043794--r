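test_that("propagator SVD satisfies its contract on random networks", {
  set.seed(61)
  for (i in 1:5) {
    N <- sample(3:8, 1)
    net <- network_model(random_stable_matrix(N, abscissa = runif(1, -0.5, 0.8)))
    t <- runif(1, 0.1, 3)
    sv <- propagator_svd(net, t)
    P <- propagator(net, t)
    expect_equal(crossprod(sv$right_vecs), diag(N), tolerance = 1e-10)
    expect_equal(crossprod(sv$left_vecs), diag(N), tolerance = 1e-10)
    expect_true(all(diff(sv$singvals) <= 0))
    expect_true(all(sv$singvals >= 0))
    # P R_k = sigma_k L_k and full reconstruction
    expect_lt(max(abs(P %*% sv$right_vecs -
                        sv$left_vecs %*% diag(sv$singvals))), 1e-10)
    rec <- sv$left_vecs %*% diag(sv$singvals) %*% t(sv$right_vecs)
    expect_lt(max(abs(rec - P)) / max(abs(P)), 1e-10)
    # deterministic sign convention
    sv2 <- propagator_svd(net, t)
    expect_identical(sv$right_vecs, sv2$right_vecs)
  }
})

test_that("normal stable networks never amplify any singular direction", {
  set.seed(62)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  lams <- c(0.8, 0.3, 0, -0.4, -0.9)
  net <- network_model(Q %*% diag(lams) %*% t(Q))
  for (t in c(0.2, 1, 3)) {
    sv <- propagator_svd(net, t)
    expect_equal(sv$singvals, exp(t * (lams - 1)), tolerance = 1e-10)
    expect_lte(sv$singvals[1], 1)
  }
})

test_that("singular value trajectories start at one with slopes from J_S", {
  set.seed(63)
  net <- network_model(random_stable_matrix(6, abscissa = 0.5, scale = 2))
  times <- seq(0, 3, length.out = 31)
  grid <- sv_trajectories(net, times)
  expect_equal(grid$singvals[, 1], rep(1, 6))
  # slopes at t = 0: finite difference cross-validation
  dt <- 1e-6
  fd <- (svd(propagator(net, dt), nu = 0, nv = 0)$d - 1) / dt
  expect_equal(sort(grid$initial_slopes), sort(fd), tolerance = 1e-4)
  expect_equal(grid$initial_slopes,
               sort(eigen(symmetric_part(net), symmetric = TRUE,
                          only.values = TRUE)$values, decreasing = TRUE) - 1)
  expect_error(sv_trajectories(net, c(0.5, 1)), "start at 0")
})

test_that("trivial slope cases and the amplified-direction count agree", {
  N <- 5
  expect_equal(initial_slopes(network_model(matrix(0, N, N))), rep(-1, N))
  # unit-rank Delta = 4: slopes {1, -1 x (N-2), -3}
  set.seed(640)
  pr <- orthonormal_pair(10)
  net <- network_model(4 * tcrossprod(pr$u, pr$v))
  expect_equal(initial_slopes(net), c(1, rep(-1, 8), -3), tolerance = 1e-12)
  set.seed(64)
  for (i in 1:50) {
    J <- matrix(rnorm(36, sd = runif(1, 0.2, 0.8)), 6, 6)
    expect_identical(sum(initial_slopes(J) > 0),
                     spectral_summary(J)$n_amplified)
  }
})

test_that("peak amplification matches dense-grid oracles", {
  # unit-rank Delta = 4
  r1 <- rank1_net(6, 4, seed = 65)
  pk <- peak_amplification(r1$net)
  ts <- seq(0.01, 5, by = 0.01)
  oracle <- vapply(ts, function(t) sigma1_oracle(r1$net$J, t), numeric(1))
  expect_equal(pk$t_star, ts[which.max(oracle)], tolerance = 0.02)
  expect_equal(pk$sigma1, max(oracle), tolerance = 1e-4)
  expect_equal(pk$t_star, 0.866, tolerance = 1e-2)
  expect_equal(pk$sigma1, 1.570, tolerance = 1e-3)
  expect_false(pk$no_amplification)
  # optimal input satisfies the vanishing-growth-rate condition
  expect_lt(abs(optimality_residual(r1$net, pk$R1)), 1e-3)

  # stable normal coupling: no amplification
  pk0 <- peak_amplification(network_model(diag(0.5, 3)))
  expect_true(pk0$no_amplification)
  expect_lte(pk0$sigma1, 1 + 1e-12)

  expect_error(peak_amplification(network_model(diag(1.2, 2))), "unstable")
})

test_that("two-population asymptotic peak agrees with the generic search", {
  p <- two_pop_from_spectrum(0, -0.25, 20) # lambda = +/- 0.5
  asym <- twopop_peak_asymptotic(p)
  expect_equal(asym$t_star, log(3), tolerance = 1e-12)
  pk <- peak_amplification(network_model(p$J))
  expect_equal(asym$sigma1 / pk$sigma1, 1, tolerance = 0.05)
  expect_equal(asym$t_star, pk$t_star, tolerance = 0.05)
})

test_that("amplified channels are orthonormal and counted correctly", {
  # unit-rank amplified: exactly one channel
  r1 <- rank1_net(8, 4, seed = 66)
  pk <- peak_amplification(r1$net)
  ch <- amplified_channels(r1$net, pk$t_star)
  expect_identical(length(ch$sigma), 1L)
  expect_gt(abs(sum(ch$readouts[, 1] * r1$u)), 0.9)
  # input and readout are distinct directions (non-normal coupling)
  expect_lt(abs(sum(ch$inputs[, 1] * ch$readouts[, 1])), 0.99)

  # two orthogonal stored patterns: two channels, readouts near u^(p)
  set.seed(67)
  spec <- lowrank_spec(12, Delta = 4, rho = 0, P = 2, mode = "exact")
  net2 <- lowrank_network(spec)
  ch2 <- amplified_channels(net2, 1)
  expect_identical(length(ch2$sigma), 2L)
  U <- cbind(spec$patterns[[1]]$u, spec$patterns[[2]]$u)
  expect_equal(crossprod(ch2$inputs), diag(2), tolerance = 1e-10)
  expect_equal(crossprod(ch2$readouts), diag(2), tolerance = 1e-10)
  # the two sigmas are exactly degenerate, so individual readout vectors are
  # defined only up to a rotation of the block; the readout SPAN must carry
  # both stored output directions
  span_proj <- crossprod(ch2$readouts, U) # 2 x 2: coords of u^(p) in the span
  expect_gt(sqrt(sum(span_proj[, 1]^2)), 0.9)
  expect_gt(sqrt(sum(span_proj[, 2]^2)), 0.9)

  # monotonic network: empty set
  ch0 <- amplified_channels(network_model(diag(0.3, 4)), 1)
  expect_identical(length(ch0$sigma), 0L)
  expect_identical(ncol(ch0$inputs), 0L)
})

test_that("optimality residual behaves as a Rayleigh-quotient diagnostic", {
  set.seed(68)
  J <- random_stable_matrix(5, abscissa = 0.3, scale = 2)
  es <- eigen(symmetric_part(J), symmetric = TRUE)
  expect_equal(optimality_residual(J, es$vectors[, 2]), es$values[2] - 1,
               tolerance = 1e-12)
  expect_error(optimality_residual(J, rep(0, 5)), "nonzero")
  expect_error(optimality_residual(J, rep(1, 5)), "unit")
  # 2D: the closed-form optimal angle zeroes the residual analytically
  p <- two_pop(0, 3, 0, 0) # lambda_S = +/- 1.5
  th <- twopop_optimal_angle(p$lambda_s[1], p$lambda_s[2])[1]
  es2 <- eigen(symmetric_part(p$J), symmetric = TRUE)
  r <- cos(th) * es2$vectors[, 1] + sin(th) * es2$vectors[, 2]
  expect_lt(abs(optimality_residual(p$J, r)), 1e-12)
})

test_that("singular value product equals the propagator determinant", {
  set.seed(69)
  for (i in 1:8) {
    N <- sample(2:7, 1)
    J <- matrix(rnorm(N * N, sd = 0.6), N, N)
    t <- runif(1, 0.1, 3)
    sv <- propagator_svd(J, t)
    expect_equal(prod(sv$singvals), exp(t * (sum(diag(J)) - N)),
                 tolerance = 1e-8)
  }
})
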