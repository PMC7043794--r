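#' Two-population network
#'
#' Builds the general two-unit coupling matrix
#' \eqn{J = [[a, b], [c, d]]} together with its derived quantities: trace,
#' determinant, eigenvalues \eqn{\lambda_\pm} of \eqn{J}, eigenvalues
#' \eqn{\lambda_{S\pm}} of the symmetric part, the non-normality parameter
#' \eqn{\Delta = |b - c| / 2} (the distance from symmetry), the critical
#' value \eqn{\Delta_c = \sqrt{\det(J - I)}} above which the network
#' (if stable) is amplified, and the relaxation timescale
#' \eqn{\tau = 1/(1 - \mathrm{Re}\,\lambda_+)}.
#'
#' @param a,b,c,d entries of the coupling matrix.
#' @return An object of class \code{two_pop} with the fields above plus the
#'   matrix \code{J}.
#' @examples
#' p <- two_pop(0, 2, 0, 0)
#' c(p$Delta, p$Delta_c)
#' @export
two_pop <- function(a, b, c, d) {
  J <- matrix(c(a, c, b, d), 2, 2)
  if (!all(is.finite(J))) stop("entries must be finite")
  tr <- a + d
  dt <- a * d - b * c
  disc <- as.complex(tr^2 - 4 * dt)
  lambda <- (tr + c(1, -1) * sqrt(disc)) / 2
  if (all(Im(lambda) == 0)) lambda <- Re(lambda)
  Delta <- abs(b - c) / 2
  lambda_s <- (tr + c(1, -1) * sqrt(tr^2 - 4 * dt + 4 * Delta^2)) / 2
  det_JI <- (a - 1) * (d - 1) - b * c
  structure(list(a = a, b = b, c = c, d = d, J = J,
                 trace = tr, det = dt,
                 lambda = lambda, lambda_s = lambda_s,
                 Delta = Delta,
                 Delta_c = if (det_JI >= 0) sqrt(det_JI) else NA_real_,
                 tau = 1 / (1 - max(Re(lambda)))),
            class = "two_pop")
}

#' @export
print.two_pop <- function(x, ...) {
  cat(sprintf("<two_pop> Tr = %g, Det = %g, Delta = %g (Delta_c = %g)\n",
              x$trace, x$det, x$Delta, x$Delta_c))
  cat("  lambda:", paste(format(x$lambda, digits = 5), collapse = ", "),
      " lambda_S:", paste(signif(x$lambda_s, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Two-population network from trace, determinant and non-normality
#'
#' Fixing \eqn{Tr(J)} and \eqn{\det(J)} fixes the eigenvalues (hence the
#' timescales) of the network; \eqn{\Delta} then tunes how far from
#' symmetric the coupling is without changing the spectrum. The canonical
#' representative has \eqn{a = d = Tr/2} and off-diagonal entries
#' \eqn{b, c = s \pm \Delta} with \eqn{s = \sqrt{\Delta^2 + Tr^2/4 - \det}}.
#'
#' @param trace,det trace and determinant of \eqn{J}.
#' @param Delta non-normality parameter \eqn{\ge 0}. For complex eigenvalues
#'   (\eqn{\det > Tr^2/4}) a real representative requires
#'   \eqn{\Delta \ge \sqrt{\det - Tr^2/4}}.
#' @return A \code{two_pop} object.
#' @export
two_pop_from_spectrum <- function(trace, det, Delta = 0) {
  stopifnot(Delta >= 0)
  q <- trace^2 / 4 - det # = b*c
  if (Delta^2 + q < 0)
    stop(sprintf(
      "no real 2x2 matrix with Tr=%g, Det=%g has Delta=%g; need Delta >= %g",
      trace, det, Delta, sqrt(-q)))
  s <- sqrt(Delta^2 + q)
  two_pop(trace / 2, s + Delta, s - Delta, trace / 2)
}

#' Spectra and regime of a two-population network
#'
#' @param p a \code{two_pop} object.
#' @param margin,stability_tol passed to [spectral_summary()].
#' @return List with \code{lambda}, \code{lambda_s}, \code{Delta},
#'   \code{Delta_c}, \code{tau} and the \code{regime} string.
#' @export
twopop_spectra <- function(p, margin = 0, stability_tol = 1e-9) {
  stopifnot(inherits(p, "two_pop"))
  summ <- spectral_summary(p$J, margin = margin, stability_tol = stability_tol)
  list(lambda = p$lambda, lambda_s = p$lambda_s, Delta = p$Delta,
       Delta_c = p$Delta_c, tau = p$tau, regime = summ$regime)
}

# x0(t), x1(t) such that exp(tJ) = x0 I + x1 J for a 2x2 J with
# eigenvalues lp, lm; analytic limit forms below the degeneracy tolerance.
.twopop_x01 <- function(lp, lm, t, degenerate_tol = 1e-8) {
  if (abs(lp - lm) < degenerate_tol) {
    l <- (lp + lm) / 2
    x0 <- exp(l * t) * (1 - l * t)
    x1 <- t * exp(l * t)
  } else {
    d <- lp - lm
    x0 <- (-lm * exp(lp * t) + lp * exp(lm * t)) / d
    x1 <- (exp(lp * t) - exp(lm * t)) / d
  }
  list(x0 = x0, x1 = x1)
}

.assert_real <- function(z, what, tol = 1e-10) {
  if (max(abs(Im(z))) > tol)
    stop(sprintf("imaginary residue %g in %s exceeds %g",
                 max(abs(Im(z))), what, tol))
  Re(z)
}

#' Closed-form propagator of the two-population network
#'
#' Evaluates \eqn{P_t = e^{-t} (x_0(t) I + x_1(t) J)}, the exact matrix
#' exponential of a 2x2 system written in terms of the eigenvalues
#' \eqn{\lambda_\pm} of \eqn{J}. Complex eigenvalues are handled in complex
#' arithmetic (the result must be real up to a 1e-10 residue); degenerate
#' eigenvalues use the analytic limit forms
#' \eqn{x_0 = e^{\lambda t}(1 - \lambda t)}, \eqn{x_1 = t e^{\lambda t}}.
#'
#' @param p a \code{two_pop} object.
#' @param t time, \eqn{t \ge 0}.
#' @param degenerate_tol eigenvalue-gap threshold for the limit forms.
#' @return The 2x2 propagator matrix.
#' @export
twopop_propagator_closed <- function(p, t, degenerate_tol = 1e-8) {
  stopifnot(inherits(p, "two_pop"), t >= 0)
  x <- .twopop_x01(p$lambda[1], p$lambda[2], t, degenerate_tol)
  P <- exp(-t) * (x$x0 * diag(2) + x$x1 * p$J)
  .assert_real(P, "twopop_propagator_closed")
}

#' Closed-form top singular value of the two-population propagator
#'
#' Evaluates \eqn{\sigma_1(P_t) = e^{-t} (\sqrt{E^2 + H^2} + |F|)} with
#' \eqn{E = x_0 + x_1 (\lambda_{S+} + \lambda_{S-})/2},
#' \eqn{F = x_1 (\lambda_{S+} - \lambda_{S-})/2} and
#' \eqn{H = x_1 \Delta}, the amplification envelope of the two-unit system.
#' For symmetric coupling (\eqn{\Delta = 0}, normal case) this reduces to
#' \eqn{e^{t(\lambda_+ - 1)}}.
#'
#' @param p a \code{two_pop} object.
#' @param t time (vectorized), \eqn{t \ge 0}.
#' @param degenerate_tol eigenvalue-gap threshold for the limit forms.
#' @return \eqn{\sigma_1(P_t)}, same length as \code{t}.
#' @export
twopop_sigma1 <- function(p, t, degenerate_tol = 1e-8) {
  stopifnot(inherits(p, "two_pop"), all(t >= 0))
  vapply(t, function(tt) {
    x <- .twopop_x01(p$lambda[1], p$lambda[2], tt, degenerate_tol)
    E <- x$x0 + x$x1 * (p$lambda_s[1] + p$lambda_s[2]) / 2
    F <- x$x1 * (p$lambda_s[1] - p$lambda_s[2]) / 2
    H <- x$x1 * p$Delta
    E <- .assert_real(E, "twopop_sigma1")
    F <- .assert_real(F, "twopop_sigma1")
    H <- .assert_real(H, "twopop_sigma1")
    exp(-tt) * (sqrt(E^2 + H^2) + abs(F))
  }, numeric(1))
}

#' Asymptotic peak amplification of the two-population network
#'
#' In the strongly non-normal regime \eqn{\Delta \gg \Delta_c} both the
#' feedforward coupling \eqn{H = x_1 \Delta} and the eigenvalue-gap term
#' \eqn{F = x_1 (\lambda_{S+} - \lambda_{S-})/2 \approx x_1 \Delta}
#' dominate the envelope, so
#' \eqn{\sigma_1(t) \approx 2 \Delta e^{-t} x_1(t)}: the peak sits at
#' \eqn{t^* = \log((\lambda_- - 1)/(\lambda_+ - 1)) / (\lambda_+ - \lambda_-)}
#' and its value
#' \eqn{\sigma_1^* = 2\Delta (r^{(\lambda_+ - 1)/d} - r^{(\lambda_- - 1)/d})/d}
#' (with \eqn{r = (\lambda_- - 1)/(\lambda_+ - 1)},
#' \eqn{d = \lambda_+ - \lambda_-}) is linear in \eqn{\Delta}. Requires real
#' stable eigenvalues; the exact numeric peak (grid + refinement on the
#' closed-form envelope) is returned alongside for error control.
#'
#' @param p a \code{two_pop} object with real \eqn{\lambda_\pm < 1}.
#' @return List: \code{t_star}, \code{sigma1} (asymptotic),
#'   \code{t_star_numeric}, \code{sigma1_numeric}, \code{valid}
#'   (\code{TRUE} when \eqn{\Delta \gg \Delta_c}, flagged at
#'   \eqn{\Delta > 5 \Delta_c}).
#' @export
twopop_peak_asymptotic <- function(p) {
  stopifnot(inherits(p, "two_pop"))
  if (is.complex(p$lambda))
    stop("asymptotic peak requires real eigenvalues; use peak_amplification")
  lp <- p$lambda[1]
  lm <- p$lambda[2]
  if (max(lp, lm) >= 1) stop("network must be stable (lambda < 1)")
  if (abs(lp - lm) < 1e-8) {
    l <- (lp + lm) / 2
    t_star <- 1 / (1 - l)
    s_star <- 2 * p$Delta * t_star * exp((l - 1) * t_star)
  } else {
    r <- (lm - 1) / (lp - 1)
    d <- lp - lm
    t_star <- log(r) / d
    s_star <- 2 * p$Delta / d * (r^((lp - 1) / d) - r^((lm - 1) / d))
  }
  grid <- seq(0, 5 * t_star + 10, length.out = 400)
  vals <- twopop_sigma1(p, grid)
  i <- which.max(vals)
  opt <- stats::optimize(function(t) -twopop_sigma1(p, t),
                         c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         tol = 1e-8)
  list(t_star = t_star, sigma1 = s_star,
       t_star_numeric = opt$minimum, sigma1_numeric = -opt$objective,
       valid = is.na(p$Delta_c) || p$Delta > 5 * p$Delta_c)
}

#' Optimal input angle of the two-unit system
#'
#' For \eqn{\lambda_{S+} > 1 > \lambda_{S-}} the optimally amplified input
#' forms the angle
#' \eqn{\theta^* = \pm \arctan\sqrt{(\lambda_{S+} - 1)/(1 - \lambda_{S-})}}
#' with the leading eigenvector of \eqn{J_S} (the vanishing point of the
#' norm growth rate).
#'
#' @param lambda_s_plus,lambda_s_minus eigenvalues of the symmetric part.
#' @return Both solutions \code{c(theta, -theta)} in radians.
#' @export
twopop_optimal_angle <- function(lambda_s_plus, lambda_s_minus) {
  if (!(lambda_s_plus > 1 && lambda_s_minus < 1))
    stop("no interior optimum: requires lambda_S+ > 1 > lambda_S- ",
         "(monotonic or unstable symmetric spectrum otherwise)")
  th <- atan(sqrt((lambda_s_plus - 1) / (1 - lambda_s_minus)))
  c(th, -th)
}

#' Excitatory-inhibitory two-population model
#'
#' One excitatory and one inhibitory population with functionally identical
#' projections: \eqn{J = [[w, -kw], [w, -kw]]} where \eqn{w > 0} is the
#' excitatory weight and \eqn{k \ge 0} the relative strength of inhibition.
#' The determinant vanishes identically (proportional rows); \eqn{k > 1} is
#' the inhibition-dominated regime.
#'
#' @param w excitatory weight, \eqn{> 0}.
#' @param k inhibition-to-excitation ratio, \eqn{\ge 0}.
#' @return A \code{two_pop} object with extra fields \code{w}, \code{k},
#'   \code{inhibition_dominated}.
#' @examples
#' p <- ei_twopop(2, 1.2)
#' p$lambda_s[1] # > 1: amplified while stable
#' @export
ei_twopop <- function(w, k) {
  stopifnot(w > 0, k >= 0)
  p <- two_pop(w, -k * w, w, -k * w)
  p$w <- w
  p$k <- k
  p$inhibition_dominated <- k > 1
  p
}

#' Regime map of the excitatory-inhibitory model
#'
#' Grids the \eqn{(w, k)} plane, classifying each point (monotonic,
#' amplified, boundary, unstable) and recording the peak amplification
#' \eqn{\sigma_1(t^*)} where the network is stable.
#'
#' @param w,k numeric grids of excitatory weights and inhibition ratios.
#' @param margin amplification margin passed to the classifier.
#' @return A data.frame with columns \code{w}, \code{k}, \code{regime},
#'   \code{sigma1_star} (\code{NA} where unstable).
#' @export
ei_phase_diagram <- function(w, k, margin = 0) {
  grid <- expand.grid(w = w, k = k)
  grid$regime <- NA_character_
  grid$sigma1_star <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- ei_twopop(grid$w[i], grid$k[i])
    sp <- twopop_spectra(p, margin = margin)
    grid$regime[i] <- sp$regime
    if (sp$regime != "unstable") {
      pk <- peak_amplification(network_model(p$J), margin = margin)
      grid$sigma1_star[i] <- pk$sigma1
    }
  }
  grid
}
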