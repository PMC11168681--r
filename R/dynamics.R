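#' Motif vector field
#'
#' Evaluates the five time-derivatives of the two-neuron / one-astrocyte
#' motif at a state, under an optional external drive `(u1, u2, v)`.
#'
#' @param state a [motif_state()] or named numeric vector with elements
#'   `x1, x2, w1, w2, z`.
#' @param params a [motif_params()].
#' @param drive numeric length-3 vector `(u1, u2, v)`; defaults to zero.
#' @return Named numeric vector of derivatives `(x1, x2, w1, w2, z)`.
#' @export
motif_vector_field <- function(state, params, drive = c(0, 0, 0)) {
  if (!all(is.finite(state))) stop("non-finite motif state", call. = FALSE)
  p <- params
  act <- p$activations
  s <- as.numeric(state)
  names(s) <- c("x1", "x2", "w1", "w2", "z")
  p1 <- act$phi(s[["x1"]])
  p2 <- act$phi(s[["x2"]])
  pz <- act$psi(s[["z"]])
  corr <- p1 * p2
  c(x1 = (-p$a1 * s[["x1"]] + s[["w2"]] * p2 + drive[[1]]) / p$tau1,
    x2 = (-p$a2 * s[["x2"]] + s[["w1"]] * p1 + drive[[2]]) / p$tau1,
    w1 = (-p$b1 * s[["w1"]] + p$c1 * corr + p$d1 * pz) / p$tau2,
    w2 = (-p$b2 * s[["w2"]] + p$c2 * corr + p$d2 * pz) / p$tau2,
    z  = (-p$eps * s[["z"]] + p$h * corr + drive[[3]]) / p$tau3)
}

#' Full hypernetwork vector field
#'
#' Evaluates the stacked neuron / synapse / astrocyte derivatives of the
#' continuous-time model: each neuron integrates `w_ij phi(x_j)` over its
#' incoming synapses; each synapse combines Hebbian drive with its assigned
#' astrocyte's output; each astrocyte combines gap-junction input, the
#' firing correlation of its monitored synapse, and the contextual signal.
#'
#' @param state a [network_state()].
#' @param params a [network_params()].
#' @param drive list with `u` (length `n`) and `v` (length `m`); defaults
#'   to zero drive.
#' @return A [network_state()]-shaped list of derivatives.
#' @export
full_vector_field <- function(state, params, drive = NULL) {
  p <- params
  if (is.null(drive)) drive <- list(u = rep(0, p$n), v = rep(0, p$m))
  x <- state$x; W <- state$W; z <- state$z
  if (length(x) != p$n || length(W) != p$o || length(z) != p$m) {
    stop("state shapes inconsistent with params", call. = FALSE)
  }
  act <- p$activations
  phx <- act$phi(x)
  psz <- act$psi(z)
  pre <- p$synapse_index[, 2]   # synapse (i,j): from j onto i
  post <- p$synapse_index[, 1]
  corr <- phx[post] * phx[pre]
  # neurons: sum incoming w_ij phi(x_j)
  syn_in <- rep(0, p$n)
  contrib <- W * phx[pre]
  for (s in seq_len(p$o)) syn_in[post[s]] <- syn_in[post[s]] + contrib[s]
  dx <- (-p$a * x + syn_in + drive$u) / p$tau_n
  dW <- (-p$b * W + p$c * corr + p$d * psz[p$synapse_astro]) / p$tau_w
  g <- p$h * corr[p$astro_synapse] + drive$v
  dz <- (-p$e * z + as.numeric(p$f %*% psz) + g) / p$tau_a
  network_state(dx, dW, dz)
}

#' Instantiate the motif as a full-network parameter set
#'
#' Returns the `n = 2`, `o = 2`, `m = 1` [network_params()] whose
#' [full_vector_field()] reproduces [motif_vector_field()] exactly, with
#' synapse 1 = `(2, 1)` (carrying `w1`, from neuron 1 onto neuron 2) and
#' synapse 2 = `(1, 2)`.
#'
#' @param params a [motif_params()].
#' @return A [network_params()].
#' @export
motif_as_network <- function(params) {
  p <- params
  network_params(
    n = 2, m = 1,
    synapse_index = rbind(c(2L, 1L), c(1L, 2L)),
    a = c(p$a1, p$a2), b = c(p$b1, p$b2), c = c(p$c1, p$c2),
    d = c(p$d1, p$d2), e = p$eps, f = matrix(0, 1, 1), h = p$h,
    synapse_astro = c(1L, 1L), astro_synapse = 1L,
    tau_n = p$tau1, tau_w = p$tau2, tau_a = p$tau3,
    activations = p$activations)
}

# Fixed-step classical Runge-Kutta-4. `f(t, y)` must accept and return the
# same shape as `y` (vector or matrix; matrix columns = ensemble members).
rk4_integrate <- function(f, y0, t_end, dt, record_every = 1L,
                          monitor = NULL) {
  stopifnot(dt > 0, t_end > 0)
  n_steps <- ceiling(t_end / dt - 1e-9)
  y <- y0
  rec_idx <- seq(0L, n_steps, by = record_every)
  if (rec_idx[length(rec_idx)] != n_steps) rec_idx <- c(rec_idx, n_steps)
  store <- vector("list", length(rec_idx))
  times <- numeric(length(rec_idx))
  store[[1]] <- y0
  ri <- 2L
  t <- 0
  for (step in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + (h / 2) * k1)
    k3 <- f(t + h / 2, y + (h / 2) * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (!all(is.finite(y))) {
      stop(sprintf("integration diverged (non-finite state) at step %d, t = %g",
                   step, t), call. = FALSE)
    }
    if (!is.null(monitor)) monitor(t, y)
    if (ri <= length(rec_idx) && step == rec_idx[ri]) {
      store[[ri]] <- y
      times[ri] <- t
      ri <- ri + 1L
    }
  }
  list(times = times, states = store)
}

#' Integrate a motif trajectory
#'
#' Fixed-step Runge-Kutta-4 integration of the motif ODEs. The default step
#' is a twentieth of the fastest time constant; a step larger than a tenth
#' of it triggers a warning.
#'
#' @param params a [motif_params()].
#' @param init a [motif_state()] (or named length-5 vector).
#' @param t_end end time (> 0), in the units of the time constants.
#' @param dt step size; default `min(tau1, tau2, tau3) / 20`.
#' @param drive `NULL` (zero), a length-3 vector `(u1, u2, v)`, or a
#'   function of time returning one.
#' @param record_every store every k-th step (the initial and final states
#'   are always stored).
#' @return A tibble with columns `t, x1, x2, w1, w2, z`.
#' @examples
#' traj <- simulate_motif(motif_params(), motif_state(1, -1, 0, 0, 0.5),
#'                        t_end = 2)
#' @export
simulate_motif <- function(params, init = motif_state(), t_end, dt = NULL,
                           drive = NULL, record_every = 1L) {
  tau_min <- min(params$tau1, params$tau2, params$tau3)
  if (is.null(dt)) dt <- tau_min / 20
  if (dt > tau_min / 10 + 1e-12) {
    warning(sprintf("dt = %g exceeds tau_min/10 = %g; integration may be inaccurate",
                    dt, tau_min / 10), call. = FALSE)
  }
  drv <- make_drive(drive, 3)
  f <- function(t, y) unname(motif_vector_field(y, params, drv(t)))
  out <- rk4_integrate(f, as.numeric(init), t_end, dt, record_every)
  states <- do.call(rbind, out$states)
  tibble::tibble(t = out$times,
                 x1 = states[, 1], x2 = states[, 2],
                 w1 = states[, 3], w2 = states[, 4], z = states[, 5])
}

#' Integrate an ensemble of motif trajectories
#'
#' Integrates many initial conditions simultaneously (vectorised over
#' ensemble columns) and returns only the final states, which is the fast
#' path for basin-of-attraction experiments.
#'
#' @inheritParams simulate_motif
#' @param inits a matrix with 5 rows (`x1, x2, w1, w2, z`), one column per
#'   initial condition.
#' @return A tibble with one row per trajectory: `id`, final
#'   `x1, x2, w1, w2, z`.
#' @export
simulate_motif_ensemble <- function(params, inits, t_end, dt = NULL,
                                    drive = NULL) {
  stopifnot(is.matrix(inits), nrow(inits) == 5)
  tau_min <- min(params$tau1, params$tau2, params$tau3)
  if (is.null(dt)) dt <- tau_min / 20
  drv <- make_drive(drive, 3)
  p <- params
  act <- p$activations
  f <- function(t, y) {
    d <- drv(t)
    p1 <- act$phi(y[1, ]); p2 <- act$phi(y[2, ]); pz <- act$psi(y[5, ])
    corr <- p1 * p2
    rbind((-p$a1 * y[1, ] + y[4, ] * p2 + d[1]) / p$tau1,
          (-p$a2 * y[2, ] + y[3, ] * p1 + d[2]) / p$tau1,
          (-p$b1 * y[3, ] + p$c1 * corr + p$d1 * pz) / p$tau2,
          (-p$b2 * y[4, ] + p$c2 * corr + p$d2 * pz) / p$tau2,
          (-p$eps * y[5, ] + p$h * corr + d[3]) / p$tau3)
  }
  out <- rk4_integrate(f, inits, t_end, dt, record_every = .Machine$integer.max)
  fin <- out$states[[length(out$states)]]
  tibble::tibble(id = seq_len(ncol(inits)),
                 x1 = fin[1, ], x2 = fin[2, ], w1 = fin[3, ], w2 = fin[4, ],
                 z = fin[5, ])
}

#' Integrate a full-network trajectory
#'
#' @param params a [network_params()].
#' @param init a [network_state()].
#' @inheritParams simulate_motif
#' @param drive `NULL`, a list `list(u =, v =)`, or a function of time
#'   returning such a list.
#' @return A tibble in wide format: `t`, `x1..xn`, `w1..wo`, `z1..zm`.
#' @export
simulate_network <- function(params, init, t_end, dt = NULL, drive = NULL,
                             record_every = 1L) {
  p <- params
  tau_min <- min(p$tau_n, p$tau_w, p$tau_a)
  if (is.null(dt)) dt <- tau_min / 20
  if (dt > tau_min / 10 + 1e-12) {
    warning(sprintf("dt = %g exceeds tau_min/10 = %g; integration may be inaccurate",
                    dt, tau_min / 10), call. = FALSE)
  }
  drv <- if (is.function(drive)) drive else function(t) drive
  pack <- function(s) c(s$x, s$W, s$z)
  unpack <- function(y) network_state(y[seq_len(p$n)],
                                      y[p$n + seq_len(p$o)],
                                      y[p$n + p$o + seq_len(p$m)])
  f <- function(t, y) pack(full_vector_field(unpack(y), p, drv(t)))
  out <- rk4_integrate(f, pack(init), t_end, dt, record_every)
  states <- do.call(rbind, out$states)
  colnames(states) <- c(paste0("x", seq_len(p$n)), paste0("w", seq_len(p$o)),
                        paste0("z", seq_len(p$m)))
  dplyr::bind_cols(tibble::tibble(t = out$times), tibble::as_tibble(states))
}

make_drive <- function(drive, len) {
  if (is.null(drive)) {
    zero <- rep(0, len)
    function(t) zero
  } else if (is.function(drive)) {
    drive
  } else {
    fixed <- rep_len(as.numeric(drive), len)
    function(t) fixed
  }
}
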