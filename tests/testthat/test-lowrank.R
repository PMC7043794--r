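test_that("structure pairs have the requested geometry", {
  expect_error(structure_pair(1.5, 10), "\\[-1, 1\\]")
  # rho = 1 duplicates the vector
  pr <- structure_pair(1, 50, seed = 81)
  expect_equal(pr$u, pr$v)
  # exact mode: unit norms and exact correlation
  for (rho in c(-0.5, 0, 0.3)) {
    pr <- structure_pair(rho, 40, seed = 82, mode = "exact")
    expect_equal(sum(pr$u^2), 1, tolerance = 1e-12)
    expect_equal(sum(pr$v^2), 1, tolerance = 1e-12)
    expect_equal(sum(pr$u * pr$v), rho, tolerance = 1e-12)
  }
  # sampled mode: near-orthogonality at large N, correlation on average
  pr <- structure_pair(0, 3000, seed = 83)
  expect_lt(abs(sum(pr$u * pr$v)), 3 / sqrt(3000))
  set.seed(84)
  rho <- 0.4
  corr <- replicate(200, {
    p <- structure_pair(rho, 200)
    sum(p$u * p$v)
  })
  expect_lt(abs(mean(corr) - rho), 3 * stats::sd(corr) / sqrt(200))
})

test_that("low-rank networks have the prescribed eigenstructure", {
  # P = 1 exact: top eigenvalue Delta * rho with eigenvector u
  for (rho in c(0, 0.2)) {
    pr <- structure_pair(rho, 30, seed = 85, mode = "exact")
    net <- lowrank_network(lowrank_spec(30, 4, rho = rho,
                                        patterns = list(pr)))
    ev <- eigen(net$J)
    expect_equal(max(Re(ev$values)), 4 * rho, tolerance = 1e-12)
    if (rho > 0) {
      top <- Re(ev$vectors[, which.max(Re(ev$values))])
      expect_gt(abs(sum(top * pr$u)), 1 - 1e-10)
    }
  }
  # rank bounded by P
  set.seed(86)
  spec <- lowrank_spec(40, 3, rho = 0, P = 5, mode = "sampled")
  net <- lowrank_network(spec)
  expect_lte(sum(svd(net$J)$d > 1e-10), 5)
  # exactly orthonormal patterns: J v^(p) = Delta u^(p)
  spec2 <- lowrank_spec(40, 3, rho = 0, P = 2, seed = 87, mode = "exact")
  net2 <- lowrank_network(spec2)
  for (p in spec2$patterns)
    expect_equal(as.numeric(net2$J %*% p$v), 3 * p$u, tolerance = 1e-12)
  expect_error(lowrank_spec(10, 2, P = 6), "2\\*P <= N")
})

test_that("unit-rank closed-form analytics match their definitions", {
  a <- rank1_analytics(4, rho = 0)
  expect_equal(a$lambda_s, c(2, -2))
  expect_true(a$amplified)
  expect_equal(a$t_star, 1)
  expect_equal(a$peak, 4 / exp(1), tolerance = 1e-12)
  expect_equal(a$align_R_v, 0.966, tolerance = 1e-3)

  a2 <- rank1_analytics(40, lambda = 0.5)
  expect_equal(a2$gain_factor, 0.5)
  expect_equal(a2$t_star, 2 * log(2), tolerance = 1e-12)

  # saturation for negative correlation
  a3 <- rank1_analytics(5000, rho = -0.1)
  expect_equal(a3$saturation, 10)
  expect_lt(a3$peak, 10)
  expect_equal(a3$peak, 10, tolerance = 0.05)

  expect_error(rank1_analytics(4, rho = 0.3), "unstable")
  expect_error(rank1_analytics(4), "either")
  # lambda -> 0 continuity of the limit forms
  expect_equal(rank1_analytics(4, lambda = 1e-9)$gain_factor,
               rank1_analytics(4, lambda = 1e-5)$gain_factor,
               tolerance = 1e-4)
})

test_that("closed-form unit-rank propagator matches the matrix exponential", {
  set.seed(91)
  for (i in 1:6) {
    N <- sample(3:10, 1)
    rho <- runif(1, -0.6, 0.2)
    Delta <- runif(1, 0.5, 5)
    pr <- structure_pair(rho, N, mode = "exact")
    t <- runif(1, 0, 3)
    P_closed <- rank1_propagator_closed(pr$u, pr$v, Delta, t)
    P_gen <- expm_oracle(t * (Delta * tcrossprod(pr$u, pr$v) - diag(N)))
    expect_lt(max(abs(P_closed - P_gen)), 1e-10)
  }
  # response from r0 = v at lambda = 0: e^{-t}(v + Delta t u)
  pr <- structure_pair(0, 20, seed = 92, mode = "exact")
  r1 <- as.numeric(rank1_propagator_closed(pr$u, pr$v, 4, 1.3) %*% pr$v)
  expect_equal(r1, exp(-1.3) * (pr$v + 4 * 1.3 * pr$u), tolerance = 1e-12)
  # orthogonal complement decays as e^{-t}
  w <- rnorm(20)
  w <- w - sum(w * pr$u) * pr$u - sum(w * pr$v) * pr$v
  rw <- as.numeric(rank1_propagator_closed(pr$u, pr$v, 4, 0.8) %*% w)
  expect_equal(rw, exp(-0.8) * w, tolerance = 1e-12)
})

test_that("closed-form unit-rank singular values match numeric SVD", {
  sv <- rank1_singvals(4, 0, 1)
  expect_equal(unname(sv[1, "sigma1"]), 1.5584, tolerance = 1e-4)
  expect_equal(unname(sv[1, "sigma2"]), 0.0869, tolerance = 1e-3)
  expect_equal(unname(sv[1, "sigma1"] * sv[1, "sigma2"]), exp(-2),
               tolerance = 1e-10)
  expect_equal(unname(rank1_singvals(3, 0.4, 0)[1, ]),
               c(1, 1), ignore_attr = TRUE)
  set.seed(93)
  for (i in 1:6) {
    Delta <- runif(1, 0.5, 6)
    rho <- runif(1, -0.5, min(0.9 / Delta, 1))
    t <- runif(1, 0.05, 3)
    pr <- structure_pair(rho, 12, mode = "exact")
    d <- svd(expm_oracle(t * (Delta * tcrossprod(pr$u, pr$v) - diag(12))),
             nu = 0, nv = 0)$d
    sv <- rank1_singvals(Delta, Delta * rho, t)
    # full spectrum: the closed-form pair plus N-2 copies of e^{-t}
    expect_equal(sort(d, decreasing = TRUE),
                 sort(c(sv[1, ], rep(exp(-t), 10)), decreasing = TRUE),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # product identity for the nontrivial pair
    expect_equal(unname(sv[1, 1] * sv[1, 2]), exp((Delta * rho - 2) * t),
                 tolerance = 1e-8)
  }
  # normal limit u = v: in-plane mode decays as e^{t(lambda-1)}
  pr <- structure_pair(1, 15, seed = 94, mode = "exact")
  lam <- 0.5
  d <- svd(expm_oracle(0.9 * (lam * tcrossprod(pr$u, pr$u) - diag(15))),
           nu = 0, nv = 0)$d
  expect_equal(max(d), exp(0.9 * (lam - 1)), tolerance = 1e-10)
})

test_that("optimal input and readout vectors align with v and u", {
  pr <- structure_pair(0, 25, seed = 95, mode = "exact")
  opt <- rank1_optimal_vectors(pr$u, pr$v, 4)
  expect_equal(sum(opt$R1^2), 1, tolerance = 1e-12)
  expect_equal(sum(opt$L1^2), 1, tolerance = 1e-12)
  expect_equal(opt$align_R_v, 0.966, tolerance = 1e-3)
  expect_equal(opt$align_L_u, 0.966, tolerance = 1e-3)
  # both lie in span(u, v)
  proj <- function(x) x - sum(x * pr$u) * pr$u - sum(x * pr$v) * pr$v
  expect_lt(sqrt(sum(proj(opt$R1)^2)), 1e-10)
  expect_lt(sqrt(sum(proj(opt$L1)^2)), 1e-10)
  # matches the generic propagator SVD at the peak
  net <- network_model(4 * tcrossprod(pr$u, pr$v))
  pk <- peak_amplification(net)
  expect_gt(abs(sum(pk$R1 * opt$R1)), 0.999)
  expect_gt(abs(sum(pk$L1 * opt$L1)), 0.999)
  # alignment grows with Delta at fixed lambda = 0
  aligns <- vapply(c(3, 5, 10, 20), function(D)
    rank1_optimal_vectors(pr$u, pr$v, D)$align_R_v, numeric(1))
  expect_true(all(diff(aligns) > 0))
  expect_gt(aligns[4], 0.99)
  expect_error(rank1_optimal_vectors(pr$u, pr$v, 1.5), "not in the amplified")
})

test_that("amplification iff-criterion on the (Delta, rho) plane", {
  set.seed(96)
  for (Delta in c(1, 2.5, 4)) {
    for (rho in c(-0.5, -0.1, 0, 0.2)) {
      if (Delta * rho >= 1) next
      pr <- structure_pair(rho, 20, mode = "exact")
      net <- network_model(Delta * tcrossprod(pr$u, pr$v))
      generic <- spectral_summary(net)$regime == "amplified"
      closed <- Delta * (rho + 1) / 2 > 1 + 1e-12
      expect_identical(generic, closed)
      expect_identical(rank1_analytics(Delta, rho = rho)$amplified, closed)
    }
  }
})

test_that("peak gain grows linearly in Delta with slope g(lambda)", {
  lam <- 0.3
  Ds <- c(10, 20, 40, 80)
  peaks <- vapply(Ds, function(D) {
    pr <- structure_pair(lam / D, 2, seed = 97, mode = "exact")
    peak_amplification(network_model(D * tcrossprod(pr$u, pr$v)),
                       t_max = 20)$sigma1
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  slope <- (peaks[4] - peaks[3]) / (Ds[4] - Ds[3])
  expect_equal(slope, (1 - lam)^(1 / lam - 1), tolerance = 0.02)
})

test_that("two stored channels stay independent", {
  set.seed(98)
  spec <- lowrank_spec(30, 4, rho = 0, P = 2, mode = "exact")
  net <- lowrank_network(spec)
  u2 <- spec$patterns[[2]]$u
  v1 <- spec$patterns[[1]]$v
  u1 <- spec$patterns[[1]]$u
  tr <- simulate_impulse(net, v1, seq(0, 3, by = 0.1))
  cross <- abs(tr$states %*% u2)
  own <- tr$states %*% u1
  expect_lt(max(cross), 1e-10)
  expect_equal(max(own), 4 / exp(1), tolerance = 1e-2)
  # trajectory confined to span(u1, v1)
  res <- tr$states -
    (tr$states %*% u1) %*% t(u1) - (tr$states %*% v1) %*% t(v1)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("storage capacity arithmetic and amplified bound", {
  expect_identical(capacity(2, 200)$P_max, 50)
  for (N in c(100, 200, 1000))
    expect_equal(capacity(2, N)$P_max, N / 4)
  cap <- capacity(1, 100)
  expect_identical(cap$P_max, 100)
  expect_false(cap$amplified)
  expect_true(capacity(2.5, 100)$amplified)
  expect_equal(capacity(3, 1000)$amplified_capacity_bound, 250)
})
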