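#' Sample a correlated structure-vector pair
#'
#' Generates the pair \eqn{(u, v)} defining a unit-rank coupling term
#' \eqn{\Delta u v^T}: \eqn{u = x_1},
#' \eqn{v = \rho x_1 + \sqrt{1 - \rho^2} x_2} with \eqn{x_1, x_2} i.i.d.
#' Gaussian vectors of entry variance \eqn{1/N}, so that on average
#' \eqn{\|u\| = \|v\| = 1} and \eqn{\langle u, v \rangle = \rho}. In
#' \code{"exact"} mode the vectors are Gram-Schmidt corrected to exact unit
#' norms and exact correlation \eqn{\rho} (deterministic geometry for unit
#' tests and designed channels).
#'
#' @param rho target correlation in \eqn{[-1, 1]}.
#' @param N dimension.
#' @param seed optional RNG seed.
#' @param mode \code{"sampled"} (norms unit on average) or \code{"exact"}.
#' @return List with unit-scale vectors \code{u} and \code{v}.
#' @export
structure_pair <- function(rho, N, seed = NULL, mode = c("sampled", "exact")) {
  mode <- match.arg(mode)
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  x1 <- stats::rnorm(N, sd = 1 / sqrt(N))
  x2 <- stats::rnorm(N, sd = 1 / sqrt(N))
  if (mode == "sampled") {
    u <- x1
    v <- rho * x1 + sqrt(1 - rho^2) * x2
  } else {
    u <- x1 / sqrt(sum(x1^2))
    w <- x2 - sum(u * x2) * u
    w <- w / sqrt(sum(w^2))
    v <- rho * u + sqrt(1 - rho^2) * w
  }
  list(u = u, v = v)
}

#' Specification of a low-rank connectivity
#'
#' A rank-\eqn{P} coupling \eqn{J = \Delta \sum_p u^{(p)} v^{(p)T}} encodes
#' \eqn{P} transient channels: a pulse along \eqn{v^{(p)}} transiently
#' activates the readout direction \eqn{u^{(p)}}. Pattern pairs are sampled
#' independently (hence nearly orthogonal across patterns at large \eqn{N});
#' \code{"exact"} mode makes all cross-pattern vectors exactly orthonormal
#' while preserving the within-pair correlation \eqn{\rho}.
#'
#' @param N dimension (\eqn{2P \le N}).
#' @param Delta scaling parameter \eqn{\Delta > 0} (a negative scale can be
#'   absorbed into \eqn{\rho}).
#' @param rho within-pair correlation.
#' @param P number of patterns.
#' @param seed optional RNG seed.
#' @param mode \code{"sampled"} or \code{"exact"}.
#' @param patterns optionally, an explicit list of \code{list(u =, v =)}
#'   pairs overriding the generator.
#' @return An object of class \code{lowrank_spec}.
#' @export
lowrank_spec <- function(N, Delta, rho = 0, P = 1, seed = NULL,
                         mode = c("sampled", "exact"), patterns = NULL) {
  mode <- match.arg(mode)
  stopifnot(Delta > 0, P >= 1)
  if (is.null(patterns)) {
    if (2 * P > N) stop("need 2*P <= N to host P independent channels")
    if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]")
    if (!is.null(seed)) set.seed(seed)
    if (mode == "sampled") {
      patterns <- replicate(P, {
        x1 <- stats::rnorm(N, sd = 1 / sqrt(N))
        x2 <- stats::rnorm(N, sd = 1 / sqrt(N))
        list(u = x1, v = rho * x1 + sqrt(1 - rho^2) * x2)
      }, simplify = FALSE)
    } else {
      # exactly orthonormal basis of the 2P-dimensional pattern subspace
      X <- matrix(stats::rnorm(N * 2 * P), N, 2 * P)
      Q <- qr.Q(qr(X))
      patterns <- lapply(seq_len(P), function(p) {
        u <- Q[, 2 * p - 1]
        list(u = u, v = rho * u + sqrt(1 - rho^2) * Q[, 2 * p])
      })
    }
  } else {
    if (length(patterns) != P) P <- length(patterns)
    N <- length(patterns[[1]]$u)
    stopifnot(all(vapply(patterns, function(p)
      length(p$u) == N && length(p$v) == N, logical(1))))
  }
  structure(list(N = N, Delta = Delta, rho = rho, P = P, seed = seed,
                 mode = mode, patterns = patterns),
            class = "lowrank_spec")
}

#' Build the network from a low-rank specification
#'
#' Returns \eqn{J = \Delta \sum_p u^{(p)} v^{(p)T}} as a
#' \code{network_model}. For \eqn{P = 1} the single nonzero eigenvalue is
#' \eqn{\lambda = \Delta \langle u, v\rangle} with eigenvector \eqn{u}; the
#' matrix rank is at most \eqn{P}.
#'
#' @param spec a \code{lowrank_spec}.
#' @return A \code{network_model}.
#' @examples
#' sp <- lowrank_spec(50, Delta = 4, rho = 0, seed = 1, mode = "exact")
#' net <- lowrank_network(sp)
#' spectral_summary(net)$regime
#' @export
lowrank_network <- function(spec) {
  stopifnot(inherits(spec, "lowrank_spec"))
  J <- matrix(0, spec$N, spec$N)
  for (p in spec$patterns)
    J <- J + tcrossprod(p$u, p$v)
  network_model(spec$Delta * J,
                label = sprintf("lowrank(Delta=%g, rho=%g, P=%d, N=%d, mode=%s)",
                                spec$Delta, spec$rho, spec$P, spec$N, spec$mode))
}

# alpha(t, lambda) = (exp(lambda t) - 1)/lambda, with series evaluation near
# lambda = 0 to avoid cancellation (alpha -> t).
alpha_rank1 <- function(t, lambda) {
  if (abs(lambda) < 1e-6)
    t * (1 + lambda * t / 2 + (lambda * t)^2 / 6)
  else
    (exp(lambda * t) - 1) / lambda
}

# peak gain factor g(lambda) = (1 - lambda)^(1/lambda - 1), g(0) = 1/e
.gain_factor <- function(lambda) {
  if (abs(lambda) < 1e-6)
    exp(-1 + lambda / 2 + lambda^2 / 6)
  else
    (1 - lambda)^(1 / lambda - 1)
}

#' Closed-form analytics of the unit-rank network
#'
#' All closed-form quantities of the family \eqn{J = \Delta u v^T} with
#' \eqn{\|u\| = \|v\| = 1}, \eqn{\langle u, v\rangle = \rho}: the nonzero
#' eigenvalue \eqn{\lambda = \Delta\rho}; the symmetric-part eigenvalues
#' \eqn{\lambda_{S\pm} = (\lambda \pm \Delta)/2} (amplified iff
#' \eqn{\Delta(\rho + 1)/2 > 1} while \eqn{\Delta\rho < 1}); the
#' strong-amplification peak time \eqn{t^* = \log(1/(1-\lambda))/\lambda}
#' (\eqn{\to 1} as \eqn{\lambda \to 0}) and peak value
#' \eqn{g(\lambda)\Delta} with \eqn{g(\lambda) = (1-\lambda)^{1/\lambda-1}};
#' the optimal input/readout angles relative to the leading mode of
#' \eqn{J_S} and the resulting alignments with \eqn{v} and \eqn{u}. For
#' fixed \eqn{\rho < 0} the peak gain saturates at \eqn{1/|\rho|} as
#' \eqn{\Delta \to \infty}.
#'
#' @param Delta scaling parameter \eqn{> 0}.
#' @param rho within-pair correlation (give either \code{rho} or
#'   \code{lambda}).
#' @param lambda the eigenvalue \eqn{\Delta\rho}; must satisfy
#'   \eqn{\lambda < 1} (stability).
#' @param scenario parameter-scaling scenario: \code{"fixed-lambda"} (fixed
#'   timescale, \eqn{\rho = \lambda/\Delta}), \code{"fixed-rho-positive"}
#'   or \code{"fixed-rho-negative"}.
#' @return An object of class \code{rank1_analytics} with fields
#'   \code{Delta}, \code{rho}, \code{lambda}, \code{lambda_s},
#'   \code{amplified}, \code{strong_amplification} (validity flag
#'   \eqn{\Delta \gg 2/(1-\lambda)}, set at 5x), \code{t_star},
#'   \code{gain_factor}, \code{peak}, \code{saturation} (for
#'   \eqn{\rho < 0}), \code{theta_R}, \code{theta_L}, \code{align_R_v},
#'   \code{align_L_u}.
#' @examples
#' a <- rank1_analytics(4, rho = 0)
#' c(a$t_star, a$peak)
#' @export
rank1_analytics <- function(Delta, rho = NULL, lambda = NULL,
                            scenario = c("fixed-lambda", "fixed-rho-positive",
                                         "fixed-rho-negative")) {
  scenario <- match.arg(scenario)
  stopifnot(Delta > 0)
  if (is.null(lambda) && is.null(rho))
    stop("give either `rho` or `lambda`")
  if (is.null(lambda)) lambda <- Delta * rho
  if (is.null(rho)) rho <- lambda / Delta
  if (abs(rho) > 1) stop("`rho` = lambda/Delta must lie in [-1, 1]")
  if (lambda >= 1)
    stop(sprintf("unstable parameters: lambda = Delta*rho = %g >= 1", lambda))
  lambda_s <- c((lambda + Delta) / 2, (lambda - Delta) / 2)
  amplified <- lambda_s[1] > 1
  theta <- NA_real_
  align <- NA_real_
  if (amplified) {
    theta <- atan(sqrt((lambda_s[1] - 1) / (1 - lambda_s[2])))
    # <R1*, v> with theta_R = -theta; <L1*, u> equals it by symmetry
    align <- cos(theta) * sqrt((1 + rho) / 2) + sin(theta) * sqrt((1 - rho) / 2)
  }
  g <- .gain_factor(lambda)
  structure(list(
    Delta = Delta, rho = rho, lambda = lambda, lambda_s = lambda_s,
    scenario = scenario,
    amplified = amplified,
    strong_amplification = Delta >= 5 * 2 / (1 - lambda),
    t_star = if (abs(lambda) < 1e-6) 1 + lambda / 2
             else log(1 / (1 - lambda)) / lambda,
    gain_factor = g,
    peak = g * Delta,
    saturation = if (rho < 0) 1 / abs(rho) else Inf,
    theta_R = -theta, theta_L = theta,
    align_R_v = align, align_L_u = align),
    class = "rank1_analytics")
}

#' @export
print.rank1_analytics <- function(x, ...) {
  cat(sprintf(
    "<rank1_analytics> Delta = %g, rho = %g (lambda = %g)\n  lambda_S: %g, %g -> %s\n  predicted t* = %.4g, peak = %.4g (strong-amplification %s)\n",
    x$Delta, x$rho, x$lambda, x$lambda_s[1], x$lambda_s[2],
    if (x$amplified) "amplified" else "not amplified",
    x$t_star, x$peak, if (x$strong_amplification) "valid" else "approximate"))
  invisible(x)
}

#' Closed-form propagator of a unit-rank network
#'
#' \eqn{P_t = e^{-t} (I + \Delta \alpha(t, \lambda) u v^T)} with
#' \eqn{\alpha(t, \lambda) = (e^{\lambda t} - 1)/\lambda}
#' (\eqn{\alpha(t, 0) = t}) and \eqn{\lambda = \Delta \langle u, v\rangle}.
#' Exact for any pair of vectors; components orthogonal to
#' \eqn{\mathrm{span}(u, v)} decay as \eqn{e^{-t}}.
#'
#' @param u,v structure vectors.
#' @param Delta scaling parameter.
#' @param t time, \eqn{t \ge 0}.
#' @return The \eqn{N \times N} propagator matrix.
#' @export
rank1_propagator_closed <- function(u, v, Delta, t) {
  stopifnot(t >= 0, length(u) == length(v))
  lambda <- Delta * sum(u * v)
  diag(exp(-t), length(u)) +
    exp(-t) * Delta * alpha_rank1(t, lambda) * tcrossprod(u, v)
}

#' Closed-form singular values of the unit-rank propagator
#'
#' The two nontrivial singular values of
#' \eqn{P_t = e^{-t}(I + \Delta\alpha u v^T)} (unit vectors, correlation
#' \eqn{\rho = \lambda/\Delta}) solve
#' \eqn{2 e^{2t} \sigma_{1,2}^2 = T \pm \sqrt{T^2 - 4 D}} with
#' \eqn{T = 2 + 2\lambda\alpha + \Delta^2\alpha^2} and
#' \eqn{D = e^{2\lambda t}}; the remaining \eqn{N - 2} singular values are
#' \eqn{e^{-t}}. The product identity
#' \eqn{\sigma_1 \sigma_2 = e^{(\lambda - 2) t}} follows.
#'
#' @param Delta scaling parameter.
#' @param lambda nonzero eigenvalue \eqn{\Delta\rho}.
#' @param t time (vectorized), \eqn{t \ge 0}.
#' @return A matrix with columns \code{sigma1}, \code{sigma2} (one row per
#'   time).
#' @examples
#' rank1_singvals(4, 0, 1)
#' @export
rank1_singvals <- function(Delta, lambda, t) {
  stopifnot(all(t >= 0))
  out <- t(vapply(t, function(tt) {
    a <- alpha_rank1(tt, lambda)
    Tq <- 2 + 2 * lambda * a + Delta^2 * a^2
    Dq <- exp(2 * lambda * tt)
    disc <- sqrt(max(Tq^2 - 4 * Dq, 0))
    exp(-tt) * sqrt(pmax(c(Tq + disc, Tq - disc), 0) / 2)
  }, numeric(2)))
  colnames(out) <- c("sigma1", "sigma2")
  out
}

#' Optimal input and readout of the unit-rank network
#'
#' Constructs \eqn{R_1^*} and \eqn{L_1^*} in the symmetric-part eigenbasis
#' \eqn{x_{S\pm} = (u \pm v)/\sqrt{2(1 \pm \rho)}}:
#' \eqn{R_1^* = \cos\theta_R^* x_{S+} + \sin\theta_R^* x_{S-}} and
#' likewise for \eqn{L_1^*} with \eqn{\theta_L^* = -\theta_R^*}. Signs are
#' fixed by requiring \eqn{\langle R_1^*, v\rangle > 0} and
#' \eqn{\langle L_1^*, u\rangle > 0}. In the strong-amplification regime the
#' optimal input aligns with the stored stimulus \eqn{v} and the optimal
#' readout with the structure vector \eqn{u}.
#'
#' @param u,v structure vectors (unit norm; exact-mode pairs recommended).
#' @param Delta scaling parameter.
#' @return List with unit vectors \code{R1}, \code{L1}, angles
#'   \code{theta_R}, \code{theta_L} and alignments \code{align_R_v},
#'   \code{align_L_u}.
#' @export
rank1_optimal_vectors <- function(u, v, Delta) {
  rho <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ana <- rank1_analytics(Delta, rho = rho)
  if (!ana$amplified)
    stop("parameters are not in the amplified regime (Delta*(rho+1)/2 <= 1)")
  xp <- (u + v) / sqrt(2 * (1 + rho))
  xm <- (u - v) / sqrt(2 * (1 - rho))
  R1 <- cos(ana$theta_R) * xp + sin(ana$theta_R) * xm
  L1 <- cos(ana$theta_L) * xp + sin(ana$theta_L) * xm
  if (sum(R1 * v) < 0) R1 <- -R1
  if (sum(L1 * u) < 0) L1 <- -L1
  R1 <- R1 / sqrt(sum(R1^2))
  L1 <- L1 / sqrt(sum(L1^2))
  list(R1 = R1, L1 = L1, theta_R = ana$theta_R, theta_L = ana$theta_L,
       align_R_v = sum(R1 * v) / sqrt(sum(v^2)),
       align_L_u = sum(L1 * u) / sqrt(sum(u^2)))
}

#' Storage capacity of a low-rank connectivity
#'
#' With \eqn{P} independently sampled patterns the bulk spectrum of
#' \eqn{J = \Delta \sum_p u^{(p)} v^{(p)T}} fills a disk of radius
#' \eqn{\Delta\sqrt{P/N}}; stability requires it below 1, giving the
#' capacity \eqn{P_{max} = \lfloor N/\Delta^2 \rfloor}. Uncorrelated
#' patterns are amplified only for \eqn{\Delta > 2}, so the capacity of an
#' amplified network is bounded by \eqn{N/4}.
#'
#' @param Delta scaling parameter \eqn{> 0}.
#' @param N network size.
#' @return List: \code{P_max}, \code{amplified} (\eqn{\Delta > 2} at
#'   \eqn{\rho = 0}), \code{amplified_capacity_bound} (= \eqn{N/4}).
#' @examples
#' capacity(2, 200)$P_max
#' @export
capacity <- function(Delta, N) {
  stopifnot(Delta > 0, N >= 2)
  list(P_max = floor(N / Delta^2),
       amplified = Delta > 2,
       amplified_capacity_bound = N / 4)
}
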