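#' Random Gaussian network
#'
#' Samples a coupling matrix with i.i.d. entries
#' \eqn{J_{ij} \sim N(0, g^2/N)}. For large \eqn{N} the eigenvalues of
#' \eqn{J} fill a disk of radius \eqn{g} (circular law) while those of the
#' symmetric part follow a semicircle of radius \eqn{\sqrt{2} g}: for
#' \eqn{1/\sqrt{2} < g < 1} the network is stable yet amplified.
#'
#' @param g coupling scale, \eqn{\ge 0}.
#' @param N network size, \eqn{\ge 2}.
#' @param seed optional RNG seed for reproducibility.
#' @return A \code{network_model} whose label records \code{(g, N, seed)}.
#' @examples
#' net <- gaussian_network(0.9, 100, seed = 1)
#' spectral_summary(net)$regime
#' @export
gaussian_network <- function(g, N, seed = NULL) {
  stopifnot(g >= 0, N >= 2)
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(stats::rnorm(N * N, sd = g / sqrt(N)), N, N)
  network_model(J, label = sprintf("gaussian(g=%g, N=%d, seed=%s)", g, N,
                                   if (is.null(seed)) "NULL" else seed))
}

#' Theoretical fraction of amplified input directions
#'
#' For the Gaussian ensemble, the fraction of eigenvalues of the symmetric
#' part exceeding \eqn{1 + \epsilon} -- a lower bound on the fraction of
#' orthogonal amplified input directions -- follows from integrating the
#' semicircle law of radius \eqn{\sqrt{2} g}:
#' \deqn{N_S(\epsilon, g)/N = \frac{1}{2}
#'   - \frac{(1+\epsilon)\sqrt{2 g^2 - (1+\epsilon)^2}}{2 \pi g^2}
#'   - \frac{1}{\pi} \arctan\frac{1+\epsilon}{\sqrt{2 g^2 - (1+\epsilon)^2}}}
#' clipped to \eqn{[0, 1/2]}; zero outside the support
#' (\eqn{(1+\epsilon)^2 > 2 g^2}). At \eqn{(\epsilon = 0, g = 1)} this
#' evaluates to 0.0908, the maximal fraction over stable coupling scales
#' (about 9\% of the network size).
#'
#' @param margin margin \eqn{\epsilon \ge 0}.
#' @param g coupling scale(s); vectorized.
#' @return The fraction \eqn{N_S(\epsilon, g)/N}.
#' @examples
#' amplified_fraction_theory(0, 1)
#' @export
amplified_fraction_theory <- function(margin = 0, g) {
  stopifnot(margin >= 0, all(g >= 0))
  a <- 1 + margin
  vapply(g, function(gg) {
    s <- 2 * gg^2 - a^2
    if (s <= 0) return(0)
    f <- 0.5 - a * sqrt(s) / (2 * pi * gg^2) - atan(a / sqrt(s)) / pi
    min(max(f, 0), 0.5)
  }, numeric(1))
}
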