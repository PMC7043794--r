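#' Singular value decomposition of the propagator
#'
#' The SVD \eqn{P_t = \sum_k \sigma_k(t) L_k(t) R_k(t)^T} resolves the
#' transient input-output structure of the network at time \eqn{t}: an input
#' along the right singular vector \eqn{R_k(t)} is mapped onto the left
#' singular vector \eqn{L_k(t)} scaled by \eqn{\sigma_k(t)}. Inputs with
#' \eqn{\sigma_k(t) > 1} are amplified at that time and \eqn{L_k(t)} is the
#' corresponding transient readout. Signs follow a deterministic convention:
#' the largest-magnitude entry of each \eqn{R_k} is positive, and \eqn{L_k}
#' follows from \eqn{P_t R_k = \sigma_k L_k}.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param t time, \eqn{t \ge 0}.
#' @return An object of class \code{propagator_svd}: \code{time},
#'   \code{singvals} (descending), \code{right_vecs}, \code{left_vecs}
#'   (orthonormal columns).
#' @examples
#' propagator_svd(network_model(matrix(c(0, 0, 4, 0), 2, 2)), 1)$singvals
#' @export
propagator_svd <- function(net, t) {
  net <- as_network(net)
  P <- propagator(net, t)
  sv <- tryCatch(svd(P), error = function(e)
    stop("SVD of the propagator failed: ", conditionMessage(e)))
  R <- sv$v
  L <- sv$u
  for (k in seq_len(ncol(R))) {
    s <- sign(R[which.max(abs(R[, k])), k])
    if (s < 0) {
      R[, k] <- -R[, k]
      L[, k] <- -L[, k]
    }
  }
  structure(list(time = t, singvals = sv$d, right_vecs = R, left_vecs = L),
            class = "propagator_svd")
}

#' Singular value trajectories of the propagator
#'
#' Tracks the singular values \eqn{\sigma_k(t)} of \eqn{P_t} over a time
#' grid. All start at 1 for \eqn{t = 0} and their initial slopes are
#' \eqn{\lambda_k(J_S) - 1}, so the number of trajectories that rise above 1
#' at small times equals the number of eigenvalues of the symmetric part
#' above 1. Values are sorted descending independently at each time point
#' (no mode tracking), so crossings appear as kinks in the rows.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param times increasing grid with \code{times[1] == 0}.
#' @return An object of class \code{sv_trajectory_grid}: \code{times},
#'   \code{singvals} (N rows, one column per time point),
#'   \code{initial_slopes}.
#' @export
sv_trajectories <- function(net, times) {
  net <- as_network(net)
  times <- as.numeric(times)
  if (times[1] != 0) stop("`times` must start at 0")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be increasing")
  sv <- vapply(times, function(t)
    svd(propagator(net, t), nu = 0, nv = 0)$d, numeric(net$N))
  structure(list(times = times, singvals = sv,
                 initial_slopes = initial_slopes(net)),
            class = "sv_trajectory_grid")
}

#' Initial slopes of the singular value trajectories
#'
#' At \eqn{t = 0} the \eqn{k}-th propagator singular value grows at rate
#' \eqn{\lambda_k(J_S) - 1}, the sorted eigenvalues of the symmetric part
#' minus one. Positive slopes flag amplified directions.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @return Numeric vector of slopes, sorted descending.
#' @export
initial_slopes <- function(net) {
  net <- as_network(net)
  sort(eigen(symmetric_part(net), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE) - 1
}

#' Peak transient amplification
#'
#' Finds the time \eqn{t^*} at which the top propagator singular value
#' \eqn{\sigma_1(t)} attains its maximum over \eqn{[0, t_{max}]}, by a
#' coarse grid search followed by golden-section refinement
#' (\code{stats::optimize}). \eqn{\sigma_1(t^*)} is the maximum amplification
#' of the network over inputs and over time; \eqn{R_1(t^*)} is the most
#' amplified input and \eqn{L_1(t^*)} the associated readout. The grid-first
#' strategy guards against local maxima, since \eqn{\sigma_1(t)} need not be
#' unimodal.
#'
#' @param net a stable \code{network_model} (spectral abscissa < 1).
#' @param t_max search horizon; default 10 effective time constants
#'   \eqn{10/(1 - \mathrm{spectral\ abscissa})}. Auto-extended once (with a
#'   warning) if the maximum sits on the boundary.
#' @param grid_size number of coarse grid points.
#' @param refine_tol tolerance of the local refinement.
#' @param margin amplification margin: if \eqn{\sigma_1(t^*) \le 1 +}
#'   \code{margin} the network is monotonic and \code{no_amplification} is
#'   set.
#' @return An object of class \code{peak_amplification}: \code{t_star},
#'   \code{sigma1}, \code{R1}, \code{L1}, \code{no_amplification}.
#' @examples
#' net <- network_model(matrix(c(0, 0, 4, 0), 2, 2))
#' pk <- peak_amplification(net)
#' c(pk$t_star, pk$sigma1)
#' @export
peak_amplification <- function(net, t_max = NULL, grid_size = 200,
                               refine_tol = 1e-6, margin = 0) {
  net <- as_network(net)
  summ <- spectral_summary(net)
  if (summ$regime == "unstable")
    stop("`net` is unstable (spectral abscissa >= 1); no peak amplification")
  if (is.null(t_max)) t_max <- 10 / (1 - summ$spectral_abscissa)
  sigma1 <- function(t) svd(propagator(net, t), nu = 0, nv = 0)$d[1]
  extend <- TRUE
  repeat {
    grid <- seq(0, t_max, length.out = grid_size)
    vals <- vapply(grid, sigma1, numeric(1))
    i <- which.max(vals)
    if (i == grid_size && extend) {
      warning("sigma1 maximum on the search boundary; extending t_max once")
      t_max <- 2 * t_max
      extend <- FALSE
    } else break
  }
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_size, i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(function(t) -sigma1(t), c(lo, hi), tol = refine_tol)
    t_star <- opt$minimum
    s_star <- -opt$objective
  } else {
    t_star <- grid[i]
    s_star <- vals[i]
  }
  if (vals[1] >= s_star) { # maximum at t = 0: monotonic decay
    t_star <- 0
    s_star <- vals[1]
  }
  sv <- propagator_svd(net, t_star)
  structure(list(t_star = t_star, sigma1 = sv$singvals[1],
                 R1 = sv$right_vecs[, 1], L1 = sv$left_vecs[, 1],
                 no_amplification = sv$singvals[1] <= 1 + margin),
            class = "peak_amplification")
}

#' @export
print.peak_amplification <- function(x, ...) {
  cat(sprintf("<peak_amplification> t* = %.4g, sigma1(t*) = %.4g%s\n",
              x$t_star, x$sigma1,
              if (x$no_amplification) " (no amplification)" else ""))
  invisible(x)
}

#' Amplified input/readout channels at a chosen time
#'
#' Extracts all singular triplets of \eqn{P_{t^*}} with
#' \eqn{\sigma_k(t^*) > 1 + \epsilon}: a set of mutually orthogonal amplified
#' input directions together with their (mutually orthogonal) transient
#' readouts. An empty set is returned for monotonic networks.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param t_star readout time, \eqn{t^* > 0} (e.g. the peak time from
#'   [peak_amplification()]).
#' @param margin amplification margin \eqn{\epsilon}.
#' @return An object of class \code{amplified_channels}: \code{t_star},
#'   \code{margin}, \code{sigma} (vector), \code{inputs} and \code{readouts}
#'   (matrices with one column per channel; zero columns when empty).
#' @export
amplified_channels <- function(net, t_star, margin = 0) {
  if (t_star <= 0) stop("`t_star` must be positive")
  sv <- propagator_svd(net, t_star)
  keep <- which(sv$singvals > 1 + margin)
  structure(list(t_star = t_star, margin = margin,
                 sigma = sv$singvals[keep],
                 inputs = sv$right_vecs[, keep, drop = FALSE],
                 readouts = sv$left_vecs[, keep, drop = FALSE]),
            class = "amplified_channels")
}

#' @export
print.amplified_channels <- function(x, ...) {
  cat(sprintf("<amplified_channels> %d channel(s) at t* = %.4g (margin %g)\n",
              length(x$sigma), x$t_star, x$margin))
  if (length(x$sigma))
    cat("  sigma:", paste(signif(x$sigma, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Optimality residual of an input direction
#'
#' The globally optimally amplified input \eqn{R_1(t^*)} satisfies
#' \eqn{r^T (J_S - I) r = 0}: at the optimum, the instantaneous norm growth
#' rate along the input vanishes. This function evaluates that residual for
#' any unit vector, as a diagnostic (for \eqn{N > 2} the condition does not
#' by itself pin down the optimal input).
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @param r unit vector (tolerance 1e-6 on the norm).
#' @return The scalar residual \eqn{r^T (J_S - I) r}.
#' @export
optimality_residual <- function(net, r) {
  r <- as.numeric(r)
  n2 <- sum(r^2)
  if (n2 == 0) stop("`r` must be nonzero")
  if (abs(sqrt(n2) - 1) > 1e-6) stop("`r` must be a unit vector")
  norm_rate(net, r)
}
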