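#' Initialise a stacked recurrent baseline agent
#'
#' Two stacked recurrent layers (vanilla tanh RNN, LSTM or GRU cells) with
#' a linear readout, trained through the same policy-gradient path as the
#' neuron-astrocyte agent. The cue is fed to layer 1 only; layer 1's output
#' feeds layer 2 through a trained matrix. Unlike the neuron-astrocyte
#' agent, all recurrent weights are trained parameters (there is no
#' plasticity-generated dynamic weight state). Weights are initialised
#' `Uniform(-1/sqrt(units), 1/sqrt(units))`.
#'
#' @param kind `"vanilla"`, `"lstm"` or `"gru"`.
#' @param units units per layer (default 128).
#' @param n_actions readout dimension.
#' @param cue_dim cue dimension (default 1).
#' @param bptt_window truncated-BPTT window, as for [init_agent()].
#' @param seed optional integer for reproducible initialisation.
#' @return An object of class `stacked_rnn_agent`.
#' @export
init_stacked_agent <- function(kind = c("vanilla", "lstm", "gru"),
                               units = 128L, n_actions = 3L, cue_dim = 1L,
                               bptt_window = 1L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(units >= 1, n_actions >= 2, bptt_window >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  gmult <- switch(kind, vanilla = 1L, lstm = 4L, gru = 3L)
  u <- as.integer(units)
  bnd <- 1 / sqrt(u)
  umat <- function(nr, nc) matrix(stats::runif(nr * nc, -bnd, bnd), nr, nc)
  params <- list(
    W1 = umat(gmult * u, u), U1 = umat(gmult * u, cue_dim),
    b1 = stats::runif(gmult * u, -bnd, bnd),
    W2 = umat(gmult * u, u), U2 = umat(gmult * u, u),
    b2 = stats::runif(gmult * u, -bnd, bnd),
    W_out = umat(n_actions, u), b_out = stats::runif(n_actions, -bnd, bnd))
  zero_state <- if (kind == "lstm") {
    list(h = rep(0, u), c = rep(0, u))
  } else {
    list(h = rep(0, u))
  }
  structure(list(kind = kind, units = u, n_actions = as.integer(n_actions),
                 cue_dim = as.integer(cue_dim),
                 bptt_window = as.integer(bptt_window),
                 params = params,
                 state = list(l1 = zero_state, l2 = zero_state),
                 buffer = list()),
            class = c("stacked_rnn_agent", "bandit_agent"))
}

#' @export
print.stacked_rnn_agent <- function(x, ...) {
  cat(sprintf("<stacked_rnn_agent> %s cells, 2 x %d units, %d actions, %d parameters\n",
              x$kind, x$units, x$n_actions,
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

# one recurrent-cell update; returns new state, output h, and cache
cell_forward <- function(kind, W, U, b, state, inp) {
  a <- as.numeric(W %*% state$h) + as.numeric(U %*% inp) + b
  u <- length(state$h)
  if (kind == "vanilla") {
    h <- tanh(a)
    list(state = list(h = h), out = h,
         cache = list(h_prev = state$h, inp = inp, h = h))
  } else if (kind == "lstm") {
    i <- sigmoid(a[1:u]); f <- sigmoid(a[u + 1:u])
    g <- tanh(a[2 * u + 1:u]); o <- sigmoid(a[3 * u + 1:u])
    c_new <- f * state$c + i * g
    tc <- tanh(c_new)
    h <- o * tc
    list(state = list(h = h, c = c_new), out = h,
         cache = list(h_prev = state$h, c_prev = state$c, inp = inp,
                      i = i, f = f, g = g, o = o, tc = tc))
  } else { # gru
    r <- sigmoid(a[1:u]); zu <- sigmoid(a[u + 1:u])
    # candidate uses the reset-gated hidden state
    an <- as.numeric(W[2 * u + 1:u, , drop = FALSE] %*% (r * state$h)) +
      as.numeric(U[2 * u + 1:u, , drop = FALSE] %*% inp) + b[2 * u + 1:u]
    nn <- tanh(an)
    h <- (1 - zu) * nn + zu * state$h
    list(state = list(h = h), out = h,
         cache = list(h_prev = state$h, inp = inp, r = r, zu = zu, nn = nn))
  }
}

# backprop one cell over a window. caches: list over steps; gout: u x K
# adjoints injected on the cell outputs. Returns grads (W, U, b) and the
# u_in x K adjoints on the inputs.
cell_backward <- function(kind, W, U, b, caches, gout) {
  K <- length(caches)
  u <- nrow(gout)
  in_dim <- nrow(U) * 0 + ncol(U)
  gW <- W * 0; gU <- U * 0; gb <- b * 0
  gin <- matrix(0, in_dim, K)
  gh_carry <- rep(0, u)
  gc_carry <- rep(0, u)
  for (s in K:1) {
    cc <- caches[[s]]
    gh <- gout[, s] + gh_carry
    if (kind == "vanilla") {
      ga <- gh * (1 - cc$h^2)
      gW <- gW + outer(ga, cc$h_prev)
      gU <- gU + outer(ga, cc$inp)
      gb <- gb + ga
      gin[, s] <- as.numeric(crossprod(U, ga))
      gh_carry <- as.numeric(crossprod(W, ga))
    } else if (kind == "lstm") {
      go <- gh * cc$tc * cc$o * (1 - cc$o)
      gc <- gc_carry + gh * cc$o * (1 - cc$tc^2)
      gi <- gc * cc$g * cc$i * (1 - cc$i)
      gf <- gc * cc$c_prev * cc$f * (1 - cc$f)
      gg <- gc * cc$i * (1 - cc$g^2)
      gc_carry <- gc * cc$f
      ga <- c(gi, gf, gg, go)
      gW <- gW + outer(ga, cc$h_prev)
      gU <- gU + outer(ga, cc$inp)
      gb <- gb + ga
      gin[, s] <- as.numeric(crossprod(U, ga))
      gh_carry <- as.numeric(crossprod(W, ga))
    } else { # gru
      gn <- gh * (1 - cc$zu)
      gzu <- gh * (cc$h_prev - cc$nn) * cc$zu * (1 - cc$zu)
      gan <- gn * (1 - cc$nn^2)
      Wn <- W[2 * u + 1:u, , drop = FALSE]
      grh <- as.numeric(crossprod(Wn, gan))
      gr <- grh * cc$h_prev
      gar <- gr * cc$r * (1 - cc$r)
      ga12 <- c(gar, gzu)
      gW[1:(2 * u), ] <- gW[1:(2 * u), ] + outer(ga12, cc$h_prev)
      gW[2 * u + 1:u, ] <- gW[2 * u + 1:u, ] + outer(gan, cc$r * cc$h_prev)
      gU[1:(2 * u), ] <- gU[1:(2 * u), ] + outer(ga12, cc$inp)
      gU[2 * u + 1:u, ] <- gU[2 * u + 1:u, ] + outer(gan, cc$inp)
      gb <- gb + c(ga12, gan)
      gin[, s] <- as.numeric(crossprod(U[1:(2 * u), , drop = FALSE], ga12)) +
        as.numeric(crossprod(U[2 * u + 1:u, , drop = FALSE], gan))
      gh_carry <- gh * cc$zu + grh * cc$r +
        as.numeric(crossprod(W[1:(2 * u), , drop = FALSE], ga12))
    }
  }
  list(W = gW, U = gU, b = gb, gin = gin)
}

#' @export
agent_step.stacked_rnn_agent <- function(agent, cue) {
  p <- agent$params
  cue <- rep_len(as.numeric(cue), agent$cue_dim)
  s1 <- cell_forward(agent$kind, p$W1, p$U1, p$b1, agent$state$l1, cue)
  s2 <- cell_forward(agent$kind, p$W2, p$U2, p$b2, agent$state$l2, s1$out)
  logits <- as.numeric(p$W_out %*% s2$out) + p$b_out
  if (!all(is.finite(logits))) stop("non-finite logits", call. = FALSE)
  rec <- list(cache1 = s1$cache, cache2 = s2$cache, h2 = s2$out)
  buf <- c(agent$buffer, list(rec))
  if (length(buf) > agent$bptt_window) {
    buf <- buf[(length(buf) - agent$bptt_window + 1):length(buf)]
  }
  agent$state <- list(l1 = s1$state, l2 = s2$state)
  agent$buffer <- buf
  list(agent = agent, logits = logits)
}

#' @export
agent_gradients.stacked_rnn_agent <- function(agent, gy) {
  p <- agent$params
  buf <- agent$buffer
  K <- length(buf)
  if (!K) stop("agent has not taken a step yet", call. = FALSE)
  gy <- as.numeric(gy)
  last <- buf[[K]]
  gout2 <- matrix(0, agent$units, K)
  gout2[, K] <- as.numeric(crossprod(p$W_out, gy))
  b2 <- cell_backward(agent$kind, p$W2, p$U2, p$b2,
                      lapply(buf, `[[`, "cache2"), gout2)
  b1 <- cell_backward(agent$kind, p$W1, p$U1, p$b1,
                      lapply(buf, `[[`, "cache1"), b2$gin)
  list(W1 = b1$W, U1 = b1$U, b1 = b1$b,
       W2 = b2$W, U2 = b2$U, b2 = b2$b,
       W_out = outer(gy, last$h2), b_out = gy)
}

# ---- classical index policies ---------------------------------------------

#' Classical bandit index policies
#'
#' `ucb_policy()` builds UCB1 or one of its non-stationary variants:
#' discounted UCB (`"ducb"`, statistics decayed geometrically each trial)
#' or sliding-window UCB (`"swucb"`, statistics over the trailing window).
#' `ts_policy()` builds Thompson sampling with per-arm Beta(1, 1) priors.
#' Use [policy_select()] then [policy_update()] each trial. All argmax
#' selections break ties toward the lowest arm index; arms without
#' (effective) pulls are forced in index order.
#'
#' @param n_arms number of arms.
#' @param variant `"ucb1"`, `"ducb"` or `"swucb"`.
#' @param discount DUCB decay factor in (0, 1\]; 1 recovers UCB1.
#' @param window SWUCB trailing-window length (>= 1); a window covering
#'   all trials recovers UCB1.
#' @return An object of class `index_policy`.
#' @export
ucb_policy <- function(n_arms, variant = c("ucb1", "ducb", "swucb"),
                       discount = 0.99, window = 1000L) {
  variant <- match.arg(variant)
  stopifnot(n_arms >= 2, discount > 0, discount <= 1, window >= 1)
  structure(list(kind = variant, n_arms = as.integer(n_arms),
                 discount = discount, window = as.integer(window),
                 counts = rep(0, n_arms), sums = rep(0, n_arms),
                 # circular buffer of (action, reward) for the sliding window
                 hist = matrix(NA_real_, window, 2), hist_pos = 0L,
                 hist_n = 0L),
            class = c(paste0(variant, "_policy"), "index_policy"))
}

#' @rdname ucb_policy
#' @export
ts_policy <- function(n_arms) {
  stopifnot(n_arms >= 2)
  structure(list(kind = "ts", n_arms = as.integer(n_arms),
                 alpha = rep(1, n_arms), beta = rep(1, n_arms)),
            class = c("ts_policy", "index_policy"))
}

#' Select an arm under an index policy
#'
#' @param policy an [ucb_policy()] or [ts_policy()].
#' @param t current trial (1-based), used by the UCB exploration bonus.
#' @return Integer arm index.
#' @export
policy_select <- function(policy, t) UseMethod("policy_select")

#' @export
policy_select.ts_policy <- function(policy, t) {
  draws <- stats::rbeta(policy$n_arms, policy$alpha, policy$beta)
  which.max(draws)
}

#' @export
policy_select.index_policy <- function(policy, t) {
  st <- ucb_statistics(policy, t)
  if (any(st$counts < 1e-12)) return(which(st$counts < 1e-12)[1])
  idx <- st$sums / st$counts + sqrt(2 * log(st$t_eff) / st$counts)
  which.max(idx)
}

# effective counts/sums and the log argument of the padding bonus;
# window statistics are maintained incrementally in policy_update()
ucb_statistics <- function(policy, t) {
  t_eff <- switch(policy$kind,
    ucb1 = max(t, 2),
    ducb = max(sum(policy$counts), 2),
    swucb = max(min(t, policy$window), 2))
  list(counts = policy$counts, sums = policy$sums, t_eff = t_eff)
}

#' Update an index policy after observing a reward
#'
#' @inheritParams policy_select
#' @param action the pulled arm.
#' @param reward the observed binary reward.
#' @return The updated policy.
#' @export
policy_update <- function(policy, action, reward) UseMethod("policy_update")

#' @export
policy_update.ts_policy <- function(policy, action, reward) {
  policy$alpha[action] <- policy$alpha[action] + reward
  policy$beta[action] <- policy$beta[action] + (1 - reward)
  policy
}

#' @export
policy_update.index_policy <- function(policy, action, reward) {
  if (policy$kind == "ducb") {
    policy$counts <- policy$discount * policy$counts
    policy$sums <- policy$discount * policy$sums
  }
  policy$counts[action] <- policy$counts[action] + 1
  policy$sums[action] <- policy$sums[action] + reward
  if (policy$kind == "swucb") {
    pos <- policy$hist_pos %% policy$window + 1L
    if (policy$hist_n == policy$window) {  # evict the oldest observation
      old <- policy$hist[pos, ]
      policy$counts[old[1]] <- policy$counts[old[1]] - 1
      policy$sums[old[1]] <- policy$sums[old[1]] - old[2]
    } else {
      policy$hist_n <- policy$hist_n + 1L
    }
    policy$hist[pos, ] <- c(action, reward)
    policy$hist_pos <- pos
  }
  policy
}
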