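#' Flattened firing-correlation vector
#'
#' For the discrete-time compact model the synaptic drive uses the full
#' `n^2` outer product of neuron outputs, `[phi(x_i) phi(x_j)]`, flattened
#' column-major (R's native order) including the diagonal. The synaptic
#' state `W` is flattened with the same convention, `W[i, j]` being the
#' weight from neuron `j` onto neuron `i`.
#'
#' @param x length-`n` neuron state.
#' @param phi neuron activation function.
#' @return Numeric vector of length `n^2`.
#' @export
phi_outer <- function(x, phi = sigmoid) {
  p <- phi(x)
  as.vector(outer(p, p))
}

#' One step of the discrete-time neuron-astrocyte map
#'
#' First-order Euler discretisation of the compact continuous model with
#' unit self-decay, step `gamma` and neuron:astrocyte time-scale ratio
#' `tau`:
#' \deqn{x^+ = (1-\gamma)x + \gamma (W\phi(x) + e_x)}
#' \deqn{W^+ = (1-\gamma)W + \gamma (C \circ \Phi(x) + D\psi(z))}
#' \deqn{z^+ = (1-\gamma\tau)z + \gamma\tau (F\psi(z) + H\Phi(x) + e_z)}
#' where `Phi(x)` is the flattened outer product [phi_outer()] and `C` acts
#' elementwise (one Hebbian gain per synapse).
#'
#' @param state list with `x` (length `n`), `W` (length `n^2`), `z`
#'   (length `m`).
#' @param C length-`n^2` elementwise Hebbian gains.
#' @param D `n^2 x m` astrocyte-to-synapse matrix.
#' @param Fmat `m x m` astrocyte coupling matrix.
#' @param H `m x n^2` synapse-to-astrocyte matrix.
#' @param gamma discretisation step, in (0, 1].
#' @param tau time-scale ratio, in (0, 1]; `tau << 1` makes astrocytes slow.
#' @param ext list with `x` (length `n`) and `z` (length `m`) external
#'   inputs; defaults to zero.
#' @param activations an [activation_triple()].
#' @return The next state, same shape as `state`.
#' @examples
#' s <- list(x = 0, W = 0, z = 0)
#' euler_discrete_step(s, C = 1, D = matrix(0, 1, 1),
#'                     Fmat = matrix(0, 1, 1), H = matrix(0, 1, 1),
#'                     gamma = 0.1, tau = 0.01)
#' @export
euler_discrete_step <- function(state, C, D, Fmat, H, gamma, tau,
                                ext = NULL, activations = activation_triple()) {
  n <- length(state$x)
  m <- length(state$z)
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]", call. = FALSE)
  if (!(tau > 0 && tau <= 1)) stop("tau must be in (0, 1]", call. = FALSE)
  if (length(state$W) != n^2) stop("W must have length n^2", call. = FALSE)
  if (length(C) != n^2 || !all(dim(as.matrix(D)) == c(n^2, m)) ||
      !all(dim(as.matrix(Fmat)) == c(m, m)) ||
      !all(dim(as.matrix(H)) == c(m, n^2))) {
    stop("coupling matrix shapes inconsistent with n, m", call. = FALSE)
  }
  if (is.null(ext)) ext <- list(x = rep(0, n), z = rep(0, m))
  act <- activations
  phx <- act$phi(state$x)
  Phi <- as.vector(outer(phx, phx))
  psz <- act$psi(state$z)
  x_new <- (1 - gamma) * state$x +
    gamma * (as.numeric(matrix(state$W, n, n) %*% phx) + ext$x)
  W_new <- (1 - gamma) * state$W + gamma * (C * Phi + as.numeric(D %*% psz))
  z_new <- (1 - gamma * tau) * state$z +
    gamma * tau * (as.numeric(Fmat %*% psz) + as.numeric(H %*% Phi) + ext$z)
  bad <- c(x = !all(is.finite(x_new)), W = !all(is.finite(W_new)),
           z = !all(is.finite(z_new)))
  if (any(bad)) {
    stop("non-finite update in component(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  list(x = x_new, W = W_new, z = z_new)
}
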