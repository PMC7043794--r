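#' Linear recurrent network model
#'
#' Wraps an \eqn{N \times N} real coupling matrix \eqn{J} for the linear rate
#' dynamics \eqn{\dot r = -r + J r + I(t) r_0} (membrane time constant
#' absorbed into the time units). Entry \code{J[i, j]} is the synaptic
#' strength from unit \code{j} onto unit \code{i}.
#'
#' @param J real square numeric matrix of couplings; all entries finite,
#'   \eqn{N \ge 2}.
#' @param label free-text provenance (ensemble name, seed, file of origin).
#' @return An object of class \code{network_model} with elements \code{J},
#'   \code{N} and \code{label}.
#' @examples
#' net <- network_model(matrix(c(0, 0, 3, 0), 2, 2), label = "feedforward")
#' net$N
#' @export
network_model <- function(J, label = "") {
  if (!is.matrix(J) || !is.numeric(J))
    stop("`J` must be a numeric matrix")
  if (nrow(J) != ncol(J))
    stop(sprintf("`J` must be square, got %d x %d", nrow(J), ncol(J)))
  if (nrow(J) < 2)
    stop("network size N must be at least 2")
  if (!all(is.finite(J)))
    stop("all entries of `J` must be finite")
  structure(list(J = J, N = nrow(J), label = as.character(label)[1]),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> N = %d%s\n", x$N,
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

# Coerce a bare matrix to a network_model; pass network_model through.
as_network <- function(net) {
  if (inherits(net, "network_model")) return(net)
  network_model(net)
}

#' Symmetric and antisymmetric parts of the coupling matrix
#'
#' \code{symmetric_part} returns \eqn{J_S = (J + J^T)/2}, whose spectrum
#' governs the instantaneous growth rate of the activity norm and therefore
#' the amplification regime of the network. \code{antisymmetric_part} returns
#' \eqn{J_A = (J - J^T)/2}; the two reconstruct \eqn{J} exactly.
#'
#' @param net a \code{network_model} (or bare square matrix).
#' @return A real matrix of the same dimension as \code{J}.
#' @examples
#' symmetric_part(network_model(matrix(c(0, 0, 2, 0), 2, 2)))
#' @export
symmetric_part <- function(net) {
  J <- as_network(net)$J
  (J + t(J)) / 2
}

#' @rdname symmetric_part
#' @export
antisymmetric_part <- function(net) {
  J <- as_network(net)$J
  (J - t(J)) / 2
}
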