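#' REINFORCE loss with a running-mean baseline
#'
#' \deqn{L_t = (\bar r_t - r_t) \log p_t^{a_t}}
#' where `r_bar` is the running mean of rewards up to and including trial
#' `t`. Minimising `L` raises the log-probability of actions whose reward
#' exceeds the running mean.
#'
#' @param r_bar running mean reward.
#' @param r reward of the taken action.
#' @param p_selected probability the policy assigned to the taken action;
#'   values at 0 are clamped to `1e-12` with a warning.
#' @return Scalar loss.
#' @examples
#' reinforce_loss(0.5, 1, 0.5)  # -0.5 * log(0.5)
#' @export
reinforce_loss <- function(r_bar, r, p_selected) {
  if (p_selected <= 0) {
    warning("p_selected clamped to 1e-12", call. = FALSE)
    p_selected <- 1e-12
  }
  if (p_selected > 1) stop("p_selected must be in (0, 1]", call. = FALSE)
  (r_bar - r) * log(p_selected)
}

#' Construct an agent or index policy by kind
#'
#' Convenience factory used by the experiment drivers and the command-line
#' interface.
#'
#' @param kind one of `"neuroastro"`, `"vrnn"`, `"lstm"`, `"gru"`,
#'   `"ucb"`, `"ts"`, `"ducb"`, `"swucb"`.
#' @param n_actions number of bandit arms.
#' @param seed integer seed for parameter initialisation.
#' @param n,m neuron-astrocyte sizes (neuroastro only).
#' @param tau,gamma time-scale ratio and step (neuroastro only).
#' @param units recurrent layer width (network baselines only).
#' @param bptt_window truncated-BPTT window (gradient agents only).
#' @param discount,window DUCB / SWUCB hyperparameters.
#' @return A `bandit_agent` or `index_policy`.
#' @export
make_agent <- function(kind, n_actions = 3L, seed = NULL,
                       n = 128L, m = 64L, tau = 0.01, gamma = 0.1,
                       units = 128L, bptt_window = 1L,
                       discount = 0.99, window = 1000L) {
  switch(kind,
    neuroastro = init_agent(n = n, m = m, n_actions = n_actions,
                            gamma = gamma, tau = tau,
                            bptt_window = bptt_window, seed = seed),
    vrnn = init_stacked_agent("vanilla", units = units,
                              n_actions = n_actions,
                              bptt_window = bptt_window, seed = seed),
    lstm = init_stacked_agent("lstm", units = units, n_actions = n_actions,
                              bptt_window = bptt_window, seed = seed),
    gru = init_stacked_agent("gru", units = units, n_actions = n_actions,
                             bptt_window = bptt_window, seed = seed),
    ucb = ucb_policy(n_actions, "ucb1"),
    ts = ts_policy(n_actions),
    ducb = ucb_policy(n_actions, "ducb", discount = discount),
    swucb = ucb_policy(n_actions, "swucb", window = window),
    stop("unknown agent kind: ", kind, call. = FALSE))
}

#' Train or run one agent on one bandit
#'
#' Runs the full trial loop: cue, recurrent step, softmax policy, action
#' sample, Bernoulli reward, running-mean baseline, REINFORCE loss and one
#' Adam update per trial (gradient agents), or the index policy's
#' select/update cycle. The trial loop draws all randomness from R's
#' global RNG, so `seed` fully determines the trace given the agent.
#'
#' @param agent a `bandit_agent` (trained by policy gradient) or an
#'   `index_policy` (no training).
#' @param spec a [bandit_spec()].
#' @param lr Adam learning rate (default 0.001); `0` disables updates.
#' @param seed optional integer seed for the trial loop (rewards and
#'   action sampling).
#' @param snapshot_every cadence (in trials) of astrocyte/synapse state
#'   snapshots, or 0 to disable. Only meaningful for the neuron-astrocyte
#'   agent.
#' @param verbose emit a progress line to stderr every 1000 trials.
#' @return An object of class `bandit_run`: `trace` tibble (one row per
#'   trial: `t, cue, action, reward, reward_mean, p_selected, loss,
#'   regret_increment, cumulative_regret`), the final `agent`, the `spec`,
#'   and optional `snapshots` (`t`, `z` matrix, `W` matrix).
#' @examples
#' spec <- bandit_spec("stationary", horizon = 200)
#' run <- train_run(init_agent(n = 8, m = 4, seed = 1), spec, seed = 1)
#' generics::glance(run)
#' @export
train_run <- function(agent, spec, lr = 0.001, seed = NULL,
                      snapshot_every = 0L, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  T_n <- spec$horizon
  is_gradient <- inherits(agent, "bandit_agent")
  opt <- if (is_gradient && lr > 0) {
    adam_optimizer(agent$params, lr = lr)
  } else NULL
  cue <- context_cue_at(spec, seq_len(T_n))
  action <- integer(T_n); reward <- numeric(T_n)
  p_sel <- numeric(T_n); loss <- numeric(T_n)
  reward_sum <- 0
  snaps_t <- integer(0); snaps_z <- list(); snaps_w <- list()
  for (t in seq_len(T_n)) {
    if (is_gradient) {
      st <- agent_step(agent, cue[t])
      agent <- st$agent
      pol <- policy_from_logits(st$logits)
      a <- select_action(pol)
      p_sel[t] <- pol$p[a]
    } else {
      a <- policy_select(agent, t)
      p_sel[t] <- NA_real_
    }
    action[t] <- a
    r <- sample_reward(spec, t, a)
    reward[t] <- r
    reward_sum <- reward_sum + r
    r_bar <- reward_sum / t
    if (is_gradient) {
      adv <- r_bar - r
      loss[t] <- adv * log(max(p_sel[t], 1e-12))
      if (!is.null(opt)) {
        gy <- adv * ((seq_len(agent$n_actions) == a) - pol$p)
        grads <- agent_gradients(agent, gy)
        upd <- adam_update(opt, agent$params, grads)
        agent$params <- upd$params
        opt <- upd$opt
      }
    } else {
      agent <- policy_update(agent, a, r)
      loss[t] <- NA_real_
    }
    if (snapshot_every > 0 && t %% snapshot_every == 0 &&
        !is.null(agent$state)) {
      snaps_t <- c(snaps_t, t)
      snaps_z[[length(snaps_z) + 1]] <- agent$state$z
      snaps_w[[length(snaps_w) + 1]] <- agent$state$W
    }
    if (verbose && t %% 1000 == 0) {
      message(sprintf("trial %d/%d", t, T_n))
    }
  }
  regret <- cumulative_regret(action, spec)
  trace <- tibble::tibble(
    t = seq_len(T_n), cue = cue, action = action, reward = reward,
    reward_mean = cumsum(reward) / seq_len(T_n),
    p_selected = p_sel, loss = loss,
    regret_increment = regret$regret_increment,
    cumulative_regret = regret$cumulative_regret)
  snapshots <- if (length(snaps_t)) {
    list(t = snaps_t, z = do.call(rbind, snaps_z),
         W = do.call(rbind, snaps_w))
  } else NULL
  structure(list(trace = trace, agent = agent, spec = spec, lr = lr,
                 seed = seed, snapshots = snapshots),
            class = "bandit_run")
}

#' @export
print.bandit_run <- function(x, ...) {
  g <- glance.bandit_run(x)
  cat(sprintf("<bandit_run> %s bandit, T = %d: cumulative regret %.1f, final-window rate %.4f/trial\n",
              x$spec$kind, x$spec$horizon, g$cumulative_regret,
              g$final_regret_rate))
  invisible(x)
}

#' @export
tidy.bandit_run <- function(x, ...) x$trace

#' Summarise a bandit run
#'
#' @param x a [train_run()] result.
#' @param final_frac fraction of final trials defining the asymptotic
#'   window (default 0.1).
#' @param ... unused.
#' @return One-row tibble: `cumulative_regret` at `T`, `final_regret_rate`
#'   (mean per-trial regret over the final window) and `mean_reward`.
#' @export
glance.bandit_run <- function(x, final_frac = 0.1, ...) {
  tr <- x$trace
  T_n <- nrow(tr)
  win <- max(1L, floor(final_frac * T_n))
  idx <- (T_n - win + 1):T_n
  tibble::tibble(
    cumulative_regret = tr$cumulative_regret[T_n],
    final_regret_rate = mean(tr$regret_increment[idx]),
    mean_reward = mean(tr$reward))
}

#' Plot the cumulative regret of one or more runs
#'
#' @param object a `bandit_run`.
#' @param ... unused.
#' @return A ggplot of cumulative regret against trial.
#' @export
autoplot.bandit_run <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$t, y = .data$cumulative_regret)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "cumulative regret") +
    ggplot2::theme_minimal()
}

derive_seed <- function(seed, i) (seed * 1009L + i * 9973L) %% 2147483647L

#' Compare agent kinds on one bandit environment
#'
#' Trains (or runs) each agent kind for `runs` seeds on the same schedule
#' and aggregates the asymptotic regret statistics across seeds
#' (unbiased standard deviation).
#'
#' @param kinds character vector of agent kinds (see [make_agent()]).
#' @param spec a [bandit_spec()].
#' @param runs seeds per kind (default 10).
#' @param seed global seed; per-run seeds are derived from it.
#' @param agent_args named list of extra arguments passed to
#'   [make_agent()] (sizes, `tau`, ...).
#' @param lr Adam learning rate for gradient agents.
#' @return A tibble with one row per kind and run
#'   (`kind, run, cumulative_regret, final_regret_rate`), with class
#'   `bandit_comparison`; summarise with [glance()][generics::glance].
#' @export
run_comparison <- function(kinds, spec, runs = 10L, seed = 1L,
                           agent_args = list(), lr = 0.001) {
  rows <- purrr::map(kinds, function(kind) {
    purrr::map(seq_len(runs), function(i) {
      s <- derive_seed(seed, i + match(kind, kinds) * 1000L)
      agent <- do.call(make_agent,
                       c(list(kind = kind, n_actions = spec$n_arms,
                              seed = s), agent_args))
      run <- train_run(agent, spec, lr = lr, seed = s + 1L)
      dplyr::bind_cols(tibble::tibble(kind = kind, run = i),
                       glance.bandit_run(run))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("bandit_comparison", class(rows))
  rows
}

#' @export
glance.bandit_comparison <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$kind),
    mean_regret = mean(.data$cumulative_regret),
    sd_regret = stats::sd(.data$cumulative_regret),
    mean_final_rate = mean(.data$final_regret_rate),
    runs = dplyr::n(), .groups = "drop")
}

#' Time-scale ablation of the neuron-astrocyte agent
#'
#' Trains the neuron-astrocyte agent at each `tau` on the same
#' environment, identical otherwise (same sizes, hence identical
#' parameter counts; `tau` changes the dynamics only).
#'
#' @param taus numeric vector of time-scale ratios in (0, 1\].
#' @param spec a [bandit_spec()] (typically flip-flop).
#' @param runs seeds per `tau`.
#' @param seed global seed.
#' @param keep_traces return the full run objects (needed for slope
#'   analysis) in addition to the summary.
#' @inheritParams run_comparison
#' @return A list with `summary` (tibble: `tau, run, cumulative_regret,
#'   final_regret_rate`) and, if requested, `runs` (nested list of
#'   `bandit_run`s indexed `[[tau]][[run]]`).
#' @export
timescale_ablation <- function(taus, spec, runs = 3L, seed = 1L,
                               agent_args = list(), lr = 0.001,
                               keep_traces = FALSE) {
  stopifnot(all(taus > 0 & taus <= 1))
  all_runs <- list()
  rows <- list()
  for (ti in seq_along(taus)) {
    tau_runs <- list()
    for (i in seq_len(runs)) {
      s <- derive_seed(seed, i + ti * 1000L)
      agent <- do.call(make_agent,
                       c(list(kind = "neuroastro", n_actions = spec$n_arms,
                              seed = s, tau = taus[ti]), agent_args))
      run <- train_run(agent, spec, lr = lr, seed = s + 1L)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(tau = taus[ti], run = i), glance.bandit_run(run))
      if (keep_traces) tau_runs[[i]] <- run
    }
    if (keep_traces) all_runs[[as.character(taus[ti])]] <- tau_runs
  }
  out <- list(summary = dplyr::bind_rows(rows))
  if (keep_traces) out$runs <- all_runs
  out
}

#' Astrocyte-to-neuron ratio sweep
#'
#' Trains neuron-astrocyte agents at fixed `n` and `m = round(ratio * n)`
#' (floored at one astrocyte) and reports mean asymptotic cumulative
#' regret per ratio.
#'
#' @param ratios astrocyte:neuron ratios `m/n`.
#' @param spec a [bandit_spec()].
#' @param n neuron count held fixed across the sweep.
#' @inheritParams timescale_ablation
#' @return A tibble `ratio, m, run, cumulative_regret, final_regret_rate`.
#' @export
ratio_sweep <- function(ratios, spec, n = 32L, runs = 3L, seed = 1L,
                        agent_args = list(), lr = 0.001) {
  rows <- list()
  for (ri in seq_along(ratios)) {
    m <- max(1L, as.integer(round(ratios[ri] * n)))
    for (i in seq_len(runs)) {
      s <- derive_seed(seed, i + ri * 1000L)
      agent <- do.call(make_agent,
                       c(list(kind = "neuroastro", n_actions = spec$n_arms,
                              seed = s, n = n, m = m), agent_args))
      run <- train_run(agent, spec, lr = lr, seed = s + 1L)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(ratio = ratios[ri], m = m, run = i),
        glance.bandit_run(run))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-phase regret slopes of a flip-flop run
#'
#' Measures the mean per-trial regret increment in a window at the start
#' of each phase of the flip-flop schedule (the first window is the
#' pre-learning slope; later windows are post-switch slopes). Used to
#' quantify catastrophic forgetting: an agent that re-learns from scratch
#' after every context switch shows post-switch slopes comparable to its
#' pre-learning slope, while an agent that retains both contexts shows
#' post-switch slopes near zero.
#'
#' @param run a [train_run()] result on a flip-flop [bandit_spec()].
#' @param window trials measured after each phase start (default
#'   `switch_period / 5`, capped at 500).
#' @return A tibble `phase_start, phase, slope`.
#' @export
flipflop_slopes <- function(run, window = NULL) {
  spec <- run$spec
  stopifnot(spec$kind == "flipflop")
  period <- spec$switch_period
  if (is.null(window)) window <- min(500L, max(50L, period %/% 5L))
  starts <- seq(1L, spec$horizon, by = period)
  inc <- run$trace$regret_increment
  purrr::map(seq_along(starts), function(i) {
    s <- starts[i]
    e <- min(s + window - 1L, spec$horizon)
    tibble::tibble(phase_start = s, phase = i - 1L,
                   slope = mean(inc[s:e]))
  }) |> dplyr::bind_rows()
}
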