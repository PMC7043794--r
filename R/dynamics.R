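#' Propagator of the linear dynamics
#'
#' Computes \eqn{P_t = \exp(t (J - I))}, the linear map taking the initial
#' state \eqn{r_0} to the state \eqn{r(t)} of \eqn{\dot r = -r + J r}.
#' Evaluated with a scaling-and-squaring matrix exponential
#' (\code{Matrix::expm}) so that defective (non-diagonalizable) couplings --
#' e.g. the nilpotent unit-rank case -- are handled without loss of accuracy.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param t time, \eqn{t \ge 0}, in units of the membrane time constant.
#' @return The \eqn{N \times N} propagator matrix.
#' @examples
#' P <- propagator(network_model(diag(0.5, 2)), 1)
#' @export
propagator <- function(net, t) {
  net <- as_network(net)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a single finite time >= 0")
  if (t == 0) return(diag(net$N))
  A <- net$J - diag(net$N)
  as.matrix(Matrix::expm(Matrix::Matrix(t * A)))
}

# Action exp(t*A) %*% v without forming the full exponential:
# scaling + truncated Taylor to machine precision. Used where only the
# image of one vector (or a few) is needed at large N.
.expm_action <- function(A, v, t = 1) {
  v <- as.numeric(v)
  if (t == 0) return(v)
  s <- max(1L, ceiling(t * max(colSums(abs(A)))))
  B <- A * (t / s)
  w <- v
  for (i in seq_len(s)) {
    term <- w
    k <- 1
    repeat {
      term <- as.numeric(B %*% term) / k
      w <- w + term
      k <- k + 1
      if (sqrt(sum(term^2)) <= 1e-16 * (1 + sqrt(sum(w^2))) || k > 200) break
    }
  }
  w
}

#' Spectral summary and amplification regime of a network
#'
#' Computes the eigenvalues of \eqn{J} and of its symmetric part
#' \eqn{J_S = (J+J^T)/2} and classifies the network. Stability requires the
#' spectral abscissa (largest real part of the eigenvalues of \eqn{J}) below
#' 1; among stable networks, amplified transients exist if and only if
#' \eqn{\lambda_{max}(J_S) > 1}: specific inputs then transiently grow in
#' norm before decaying. \code{n_amplified} counts the eigenvalues of
#' \eqn{J_S} above \eqn{1 + \epsilon}, a lower bound on the number of
#' orthogonal amplified input directions.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param margin amplification margin \eqn{\epsilon \ge 0}; the regime is
#'   \code{"boundary"} when \eqn{|\lambda_{max}(J_S) - 1| \le \epsilon}.
#' @param stability_tol tolerance on the stability comparison of the spectral
#'   abscissa with 1.
#' @return An object of class \code{spectral_summary}: \code{eigs_full}
#'   (complex eigenvalues of \eqn{J}), \code{eigs_sym} (real eigenvalues of
#'   \eqn{J_S}, descending), \code{spectral_abscissa}, \code{lambda_max_sym},
#'   \code{regime} (one of \code{"unstable"}, \code{"amplified"},
#'   \code{"boundary"}, \code{"monotonic"}), \code{n_amplified},
#'   \code{margin}.
#' @examples
#' spectral_summary(network_model(matrix(c(0, 0, 3, 0), 2, 2)))
#' @export
spectral_summary <- function(net, margin = 0, stability_tol = 1e-9) {
  net <- as_network(net)
  stopifnot(margin >= 0)
  eigs_full <- tryCatch(eigen(net$J, only.values = TRUE)$values,
                        error = function(e)
                          stop("eigen-solver failed on J: ", conditionMessage(e)))
  eigs_sym <- tryCatch(
    eigen(symmetric_part(net), symmetric = TRUE, only.values = TRUE)$values,
    error = function(e)
      stop("eigen-solver failed on J_S: ", conditionMessage(e)))
  eigs_sym <- sort(eigs_sym, decreasing = TRUE)
  sa <- max(Re(eigs_full))
  lms <- eigs_sym[1]
  regime <- if (sa >= 1 - stability_tol) {
    "unstable"
  } else if (lms > 1 + margin) {
    "amplified"
  } else if (abs(lms - 1) <= margin) {
    "boundary"
  } else {
    "monotonic"
  }
  structure(list(eigs_full = eigs_full,
                 eigs_sym = eigs_sym,
                 spectral_abscissa = sa,
                 lambda_max_sym = lms,
                 regime = regime,
                 n_amplified = sum(eigs_sym > 1 + margin),
                 margin = margin),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(
    "<spectral_summary> regime: %s\n  spectral abscissa: %.6g\n  lambda_max(J_S): %.6g\n  amplified directions N_S(eps=%g): %d\n",
    x$regime, x$spectral_abscissa, x$lambda_max_sym, x$margin, x$n_amplified))
  invisible(x)
}

#' Instantaneous relative growth rate of the activity norm
#'
#' Evaluates \eqn{(1/\|r\|) d\|r\|/dt = r^T (J_S - I) r / \|r\|^2}, a
#' Rayleigh quotient of the shifted symmetric part. Its maximum over
#' directions is \eqn{\lambda_{max}(J_S) - 1}, so the norm of the activity
#' can grow at some instant if and only if \eqn{\lambda_{max}(J_S) > 1}.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param r nonzero activity vector (any scale; the quotient is
#'   scale-invariant).
#' @return The scalar growth rate.
#' @examples
#' norm_rate(network_model(matrix(c(0, 0, 3, 0), 2, 2)), c(1, 1))
#' @export
norm_rate <- function(net, r) {
  net <- as_network(net)
  r <- as.numeric(r)
  n2 <- sum(r^2)
  if (!all(is.finite(r)) || n2 == 0)
    stop("`r` must be a finite nonzero vector")
  JS <- symmetric_part(net)
  as.numeric(crossprod(r, JS %*% r)) / n2 - 1
}

#' Impulse-response trajectory
#'
#' Simulates the response to a pulse input along a unit direction
#' \eqn{r_0}, i.e. the trajectory \eqn{r(t) = P_t r_0}. States are evaluated
#' exactly through the propagator (one matrix exponential per distinct grid
#' step, then semigroup stepping), so there is no time-discretization error.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param r0 input direction; renormalized to unit norm with a warning unless
#'   already unit (tolerance 1e-8).
#' @param times increasing time grid starting at 0.
#' @param normalize if \code{FALSE}, \code{r0} is used exactly as given
#'   (bypass for linear-scaling studies).
#' @return An object of class \code{trajectory_record}: \code{times},
#'   \code{states} (matrix, one row per time point), \code{norms},
#'   \code{initial_condition}.
#' @examples
#' tr <- simulate_impulse(network_model(diag(0, 2)), c(1, 0), seq(0, 2, 0.5))
#' tr$norms
#' @export
simulate_impulse <- function(net, r0, times, normalize = TRUE) {
  net <- as_network(net)
  r0 <- as.numeric(r0)
  if (length(r0) != net$N) stop("`r0` must have length N")
  nrm <- sqrt(sum(r0^2))
  if (nrm == 0) stop("`r0` must be nonzero")
  if (normalize && abs(nrm - 1) > 1e-8) {
    warning("`r0` renormalized to unit norm")
    r0 <- r0 / nrm
  }
  times <- as.numeric(times)
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("`times` must be strictly increasing and nonnegative")
  A <- net$J - diag(net$N)
  states <- matrix(NA_real_, length(times), net$N)
  # semigroup stepping: one expm per distinct step length
  dts <- c(times[1], diff(times))
  cache <- list()
  r <- r0
  for (k in seq_along(times)) {
    dt <- dts[k]
    if (dt > 0) {
      key <- sprintf("%.17g", dt)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.matrix(Matrix::expm(Matrix::Matrix(dt * A)))
      r <- as.numeric(cache[[key]] %*% r)
    }
    states[k, ] <- r
  }
  structure(list(times = times, states = states,
                 norms = sqrt(rowSums(states^2)),
                 initial_condition = r0),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record> N = %d, %d time points on [%g, %g], peak norm %.4g\n",
              ncol(x$states), length(x$times), min(x$times), max(x$times),
              max(x$norms)))
  invisible(x)
}
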