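#' Initialise a trainable discrete-time neuron-astrocyte agent
#'
#' Builds the discrete-time network (one update per bandit trial)
#' \deqn{x_t = (1-\gamma)x_{t-1} + \gamma (W_{t-1}\phi(x_{t-1}) + W_{in1} I_t)}
#' \deqn{W_t = (1-\gamma)W_{t-1} + \gamma (C \circ \Phi(x_{t-1}) + D\psi(z_{t-1}))}
#' \deqn{z_t = (1-\gamma\tau)z_{t-1} + \gamma\tau (F\psi(z_{t-1}) + H\Phi(x_{t-1}) + W_{in2} I_t)}
#' \deqn{y_t = W_{out} x_t + b_{out}}
#' The synaptic matrix `W_t` is dynamic *state*, generated by the
#' plasticity rule; the trained parameters are the plasticity/coupling
#' matrices `C, D, F, H`, the input maps `W_in1, W_in2` and the readout
#' `W_out, b_out`. `C, D, F, H` entries are drawn `Normal(0, 1)/sqrt(N)`
#' and the input/output maps `Uniform(-1/sqrt(N), 1/sqrt(N))`, with `N` the
#' fan-in of each matrix. The dynamic state starts at zero.
#'
#' @param n neurons (default 128).
#' @param m astrocytes (default 64).
#' @param n_actions readout dimension (default 3).
#' @param cue_dim dimension of the contextual cue (default 1, scalar cues).
#' @param gamma discretisation step in (0, 1] (default 0.1).
#' @param tau neuron:astrocyte time-scale ratio in (0, 1] (default 0.01).
#' @param bptt_window number of past trials gradients are propagated
#'   through (truncated backpropagation-through-time; 1 = within-trial
#'   only).
#' @param seed optional integer; when given, initialisation is drawn from a
#'   private RNG stream and is bitwise reproducible.
#' @param activations an [activation_triple()].
#' @return An object of class `neuroastro_agent`.
#' @examples
#' ag <- init_agent(n = 8, m = 4, seed = 1)
#' st <- agent_step(ag, cue = 1)
#' policy_from_logits(st$logits)
#' @export
init_agent <- function(n = 128L, m = 64L, n_actions = 3L, cue_dim = 1L,
                       gamma = 0.1, tau = 0.01, bptt_window = 1L,
                       seed = NULL, activations = activation_triple()) {
  stopifnot(n >= 1, m >= 1, n_actions >= 2, cue_dim >= 1,
            gamma > 0, gamma <= 1, tau > 0, tau <= 1, bptt_window >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n2 <- n * n
  normal_mat <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc) / sqrt(fan_in), nr, nc)
  }
  unif_mat <- function(nr, nc, fan_in) {
    b <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -b, b), nr, nc)
  }
  params <- list(
    W_in1 = unif_mat(n, cue_dim, cue_dim),
    W_in2 = unif_mat(m, cue_dim, cue_dim),
    # C acts as a diagonal map on the n^2-dim correlation vector, so its
    # fan-in under the 1/sqrt(N) rule is n^2
    C = stats::rnorm(n2) / n,
    D = normal_mat(n2, m, m),
    F = normal_mat(m, m, m),
    H = normal_mat(m, n2, n2),
    W_out = unif_mat(n_actions, n, n),
    b_out = stats::runif(n_actions, -1 / sqrt(n), 1 / sqrt(n)))
  structure(list(n = as.integer(n), m = as.integer(m),
                 n_actions = as.integer(n_actions),
                 cue_dim = as.integer(cue_dim),
                 gamma = gamma, tau = tau,
                 bptt_window = as.integer(bptt_window),
                 params = params,
                 state = list(x = rep(0, n), W = rep(0, n2), z = rep(0, m)),
                 buffer = list(),
                 activations = activations),
            class = c("neuroastro_agent", "bandit_agent"))
}

#' @export
print.neuroastro_agent <- function(x, ...) {
  cat(sprintf("<neuroastro_agent> n = %d neurons, m = %d astrocytes, %d actions\n",
              x$n, x$m, x$n_actions))
  cat(sprintf("  gamma = %g, tau = %g, bptt window = %d, %d trainable arrays (%d values)\n",
              x$gamma, x$tau, x$bptt_window, length(x$params),
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

#' Advance an agent by one trial
#'
#' Generic over agent kinds: applies one recurrent update driven by the
#' contextual cue and returns the action logits. The returned agent carries
#' the updated dynamic state and the cached quantities needed for
#' [agent_gradients()].
#'
#' @param agent a `bandit_agent`.
#' @param cue numeric cue vector (length `cue_dim`).
#' @return A list with elements `agent` (updated) and `logits`
#'   (length `n_actions`).
#' @export
agent_step <- function(agent, cue) UseMethod("agent_step")

#' @export
agent_step.neuroastro_agent <- function(agent, cue) {
  p <- agent$params
  st <- agent$state
  act <- agent$activations
  g <- agent$gamma; gt <- agent$gamma * agent$tau
  n <- agent$n
  cue <- rep_len(as.numeric(cue), agent$cue_dim)
  phx <- act$phi(st$x)
  Phi <- as.vector(outer(phx, phx))
  psz <- act$psi(st$z)
  Wm <- matrix(st$W, n, n)
  x_new <- (1 - g) * st$x + g * (as.numeric(Wm %*% phx) + as.numeric(p$W_in1 %*% cue))
  W_new <- (1 - g) * st$W + g * (p$C * Phi + as.numeric(p$D %*% psz))
  z_new <- (1 - gt) * st$z +
    gt * (as.numeric(p$F %*% psz) + as.numeric(p$H %*% Phi) + as.numeric(p$W_in2 %*% cue))
  for (nm in c("x", "W", "z")) {
    v <- switch(nm, x = x_new, W = W_new, z = z_new)
    if (!all(is.finite(v))) {
      stop("non-finite agent state in component ", nm, call. = FALSE)
    }
  }
  logits <- as.numeric(p$W_out %*% x_new) + p$b_out
  rec <- list(x_prev = st$x, W_prev = st$W, z_prev = st$z,
              phx = phx, psz = psz, cue = cue, x_new = x_new)
  buf <- c(agent$buffer, list(rec))
  if (length(buf) > agent$bptt_window) {
    buf <- buf[(length(buf) - agent$bptt_window + 1):length(buf)]
  }
  agent$state <- list(x = x_new, W = W_new, z = z_new)
  agent$buffer <- buf
  list(agent = agent, logits = logits)
}

#' Gradients of a scalar loss with respect to the trained parameters
#'
#' Backpropagates the logit-gradient `gy` of the most recent trial through
#' the cached window of recurrent steps (truncated BPTT). The state
#' carried into the window is treated as constant.
#'
#' @param agent a `bandit_agent` that has taken at least one step.
#' @param gy gradient of the loss with respect to the latest logits
#'   (length `n_actions`).
#' @return A named list of gradients matching `agent$params`.
#' @export
agent_gradients <- function(agent, gy) UseMethod("agent_gradients")

#' @export
agent_gradients.neuroastro_agent <- function(agent, gy) {
  p <- agent$params
  act <- agent$activations
  buf <- agent$buffer
  K <- length(buf)
  if (!K) stop("agent has not taken a step yet", call. = FALSE)
  n <- agent$n; m <- agent$m; n2 <- n * n
  g <- agent$gamma; gt <- agent$gamma * agent$tau
  last <- buf[[K]]
  gy <- as.numeric(gy)
  grads <- list(W_out = outer(gy, last$x_new), b_out = gy)
  # adjoints of the state entering step s (columns = window position)
  gx <- as.numeric(crossprod(p$W_out, gy))
  gW <- rep(0, n2)
  gz <- rep(0, m)
  GX <- matrix(0, n, K); GW <- matrix(0, n2, K); GZ <- matrix(0, m, K)
  tH <- t(p$H); tD <- t(p$D); tF <- t(p$F)
  for (s in K:1) {
    GX[, s] <- gx; GW[, s] <- gW; GZ[, s] <- gz
    rec <- buf[[s]]
    phx <- rec$phx
    dphx <- act$dphi(rec$x_prev)
    dpsz <- act$dpsi(rec$z_prev)
    gPhi <- g * (p$C * gW) + gt * as.numeric(tH %*% gz)
    V <- matrix(gPhi, n, n)
    gx_prev <- (1 - g) * gx +
      g * dphx * as.numeric(crossprod(matrix(rec$W_prev, n, n), gx)) +
      dphx * as.numeric((V + t(V)) %*% phx)
    gW_prev <- (1 - g) * gW + g * as.vector(outer(gx, phx))
    gz_prev <- (1 - gt) * gz +
      dpsz * (g * as.numeric(tD %*% gW) + gt * as.numeric(tF %*% gz))
    gx <- gx_prev; gW <- gW_prev; gz <- gz_prev
  }
  PhiM <- vapply(buf, function(r) as.vector(outer(r$phx, r$phx)),
                 numeric(n2))
  PhiM <- matrix(PhiM, n2, K)
  PszM <- matrix(vapply(buf, `[[`, numeric(m), "psz"), m, K)
  CueM <- matrix(vapply(buf, `[[`, numeric(agent$cue_dim), "cue"),
                 agent$cue_dim, K)
  grads$W_in1 <- g * (GX %*% t(CueM))
  grads$W_in2 <- gt * (GZ %*% t(CueM))
  grads$C <- g * rowSums(GW * PhiM)
  grads$D <- g * (GW %*% t(PszM))
  grads$F <- gt * (GZ %*% t(PszM))
  grads$H <- gt * (GZ %*% t(PhiM))
  grads[names(p)]
}

#' Softmax policy from logits
#'
#' @param y numeric logits.
#' @return An object of class `policy_output`: list with `logits` and
#'   probability vector `p` (positive, summing to one; computed with
#'   max-subtraction for overflow safety).
#' @export
policy_from_logits <- function(y) {
  if (!all(is.finite(y))) stop("non-finite logits", call. = FALSE)
  e <- exp(y - max(y))
  structure(list(logits = y, p = e / sum(e)), class = "policy_output")
}

#' Sample an action from a policy
#'
#' Categorical draw using R's global RNG stream (one `runif` per call, so
#' seeded runs are reproducible).
#'
#' @param policy a [policy_from_logits()] result or a probability vector.
#' @return Integer action index.
#' @export
select_action <- function(policy) {
  p <- if (inherits(policy, "policy_output")) policy$p else as.numeric(policy)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("invalid probability vector", call. = FALSE)
  }
  findInterval(stats::runif(1), cumsum(p), left.open = TRUE) + 1L
}

# ---- RNG helpers -----------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# ---- checkpoints -----------------------------------------------------------

#' Save or load agent parameters as a JSON checkpoint
#'
#' The checkpoint is a JSON manifest holding shapes, hyperparameters and
#' flattened parameter arrays; the dynamic state is saved too so a training
#' run can be resumed.
#'
#' @param agent a `neuroastro_agent`.
#' @param path file path (`.json`).
#' @return `save_agent()` returns `path` invisibly; `load_agent()` returns
#'   the reconstructed agent.
#' @export
save_agent <- function(agent, path) {
  obj <- list(kind = class(agent)[1],
              n = agent$n, m = agent$m, n_actions = agent$n_actions,
              cue_dim = agent$cue_dim, gamma = agent$gamma, tau = agent$tau,
              bptt_window = agent$bptt_window,
              params = lapply(agent$params, function(x) {
                list(dim = if (is.matrix(x)) dim(x) else length(x),
                     data = as.numeric(x))
              }),
              state = agent$state)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  agent <- init_agent(n = obj$n, m = obj$m, n_actions = obj$n_actions,
                      cue_dim = obj$cue_dim, gamma = obj$gamma,
                      tau = obj$tau, bptt_window = obj$bptt_window, seed = 0)
  agent$params <- lapply(obj$params, function(pp) {
    if (length(pp$dim) == 2) matrix(pp$data, pp$dim[1], pp$dim[2]) else pp$data
  })
  agent$state <- list(x = as.numeric(obj$state$x),
                      W = as.numeric(obj$state$W),
                      z = as.numeric(obj$state$z))
  agent
}
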