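#' Activation functions for neurons, astrocytes and schedules
#'
#' The model uses three scalar nonlinearities: `phi` maps a neuron's mean
#' membrane potential to a firing-rate surrogate in \[0, 1\]; `psi` maps an
#' astrocyte's calcium-wave activity to a graded output in \[-1, 1\]; `S` is
#' the sigmoid used by the smooth-changing bandit schedule, mapping into
#' (0, 1). The defaults are the logistic sigmoid for `phi` and `S` and the
#' hyperbolic tangent for `psi`.
#'
#' @param phi neuron activation, a vectorised function of a numeric vector.
#' @param psi astrocyte activation, a vectorised function.
#' @param S schedule sigmoid, a vectorised function.
#'
#' @return An object of class `activation_triple`: a list with elements
#'   `phi`, `psi`, `S` and their derivatives `dphi`, `dpsi`.
#' @examples
#' act <- activation_triple()
#' act$phi(0)  # 0.5
#' act$psi(0)  # 0
#' @export
activation_triple <- function(phi = sigmoid, psi = tanh, S = sigmoid) {
  stopifnot(is.function(phi), is.function(psi), is.function(S))
  dphi <- if (identical(phi, sigmoid)) {
    function(x) { p <- sigmoid(x); p * (1 - p) }
  } else {
    function(x) num_deriv(phi, x)
  }
  dpsi <- if (identical(psi, tanh)) {
    function(z) 1 - tanh(z)^2
  } else {
    function(z) num_deriv(psi, z)
  }
  structure(list(phi = phi, psi = psi, S = S, dphi = dphi, dpsi = dpsi),
            class = "activation_triple")
}

#' Logistic sigmoid
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate one of the model's activation maps by name
#'
#' @param triple an [activation_triple()].
#' @param value numeric vector to map.
#' @param which one of `"phi"`, `"psi"`, `"S"`.
#' @return The chosen map applied to `value`.
#' @export
evaluate_activation <- function(triple, value, which = c("phi", "psi", "S")) {
  if (!inherits(triple, "activation_triple")) {
    stop("`triple` must be an activation_triple", call. = FALSE)
  }
  which <- match.arg(which)
  triple[[which]](value)
}

# central finite difference, used only for non-default activations
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
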