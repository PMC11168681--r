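#' Specify a (possibly non-stationary) Bernoulli bandit
#'
#' Three schedule kinds are supported. `"stationary"`: constant arm means.
#' `"flipflop"`: one arm's mean alternates between two values every
#' `switch_period` trials while the other arms stay fixed, so the identity
#' of the best arm flips. `"smooth"`: all means follow the smooth periodic
#' schedule
#' \deqn{\mu_i(t) = \mu_i^* \, S(Q \sin(2\pi t / P + 2\pi i / n))}
#' with `S` the sigmoid; for large `Q` this approximates a square wave and
#' the best arm rotates once per period. Alongside the means, each spec
#' defines a scalar contextual-cue stream that signals the current context
#' without revealing the arm probabilities (stationary: always 1;
#' flip-flop: -1/+1 by phase; smooth: which arm is currently best, encoded
#' on `[-1, 1]`).
#'
#' @param kind `"stationary"`, `"flipflop"` or `"smooth"`.
#' @param horizon total number of trials `T`.
#' @param means stationary per-arm means in \[0, 1\] (also the fixed means
#'   of the non-switching arms in the flip-flop schedule).
#' @param switch_arm flip-flop: index of the switching arm.
#' @param switch_means flip-flop: the two alternating means `(mu, mu')`;
#'   phase 0 starts at the first.
#' @param switch_period flip-flop: trials per phase.
#' @param mu_star smooth: per-arm amplitudes `mu_i^*` in \[0, 1\].
#' @param P,Q smooth: period (trials) and sigmoid gain.
#' @param S schedule sigmoid (default the logistic).
#' @return An object of class `bandit_spec`.
#' @examples
#' spec <- bandit_spec("flipflop", horizon = 1000, switch_period = 250)
#' arm_means_at(spec, 1)
#' context_cue_at(spec, c(1, 251))
#' @export
bandit_spec <- function(kind = c("stationary", "flipflop", "smooth"),
                        horizon = 5000L,
                        means = c(0.4, 0.8, 0.1),
                        switch_arm = 2L,
                        switch_means = c(0.92, 0.042),
                        switch_period = 5000L,
                        mu_star = rep(0.9, length(means)),
                        P = 10000, Q = 100,
                        S = sigmoid) {
  kind <- match.arg(kind)
  n_arms <- length(means)
  stopifnot(n_arms >= 2, horizon >= 1)
  if (any(means < 0 | means > 1) || any(mu_star < 0 | mu_star > 1) ||
      any(switch_means < 0 | switch_means > 1)) {
    stop("all arm means must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "flipflop") {
    stopifnot(switch_arm >= 1, switch_arm <= n_arms, switch_period >= 1,
              length(switch_means) == 2)
  }
  if (kind == "smooth") stopifnot(P > 0, Q > 0, length(mu_star) == n_arms)
  structure(list(kind = kind, n_arms = n_arms, horizon = as.integer(horizon),
                 means = means, switch_arm = as.integer(switch_arm),
                 switch_means = switch_means,
                 switch_period = as.integer(switch_period),
                 mu_star = mu_star, P = P, Q = Q, S = S),
            class = "bandit_spec")
}

#' @export
print.bandit_spec <- function(x, ...) {
  cat(sprintf("<bandit_spec> %s Bernoulli bandit, %d arms, T = %d\n",
              x$kind, x$n_arms, x$horizon))
  invisible(x)
}

check_trials <- function(spec, t) {
  if (any(t < 1 | t > spec$horizon)) {
    stop("trial index out of range 1..T", call. = FALSE)
  }
  as.integer(t)
}

#' Arm means at given trials
#'
#' @param spec a [bandit_spec()].
#' @param t trial index (1-based). May be a vector.
#' @return For scalar `t`, the per-arm mean vector; for vector `t`, a
#'   `length(t) x n_arms` matrix.
#' @export
arm_means_at <- function(spec, t) {
  t <- check_trials(spec, t)
  M <- switch(spec$kind,
    stationary = matrix(spec$means, length(t), spec$n_arms, byrow = TRUE),
    flipflop = {
      M <- matrix(spec$means, length(t), spec$n_arms, byrow = TRUE)
      phase <- ((t - 1L) %/% spec$switch_period) %% 2L
      M[, spec$switch_arm] <- spec$switch_means[phase + 1L]
      M
    },
    smooth = {
      i <- seq_len(spec$n_arms)
      ang <- outer(2 * pi * t / spec$P, 2 * pi * i / spec$n_arms, "+")
      sweep(spec$S(spec$Q * sin(ang)), 2, spec$mu_star, "*")
    })
  if (length(t) == 1) drop(M) else M
}

#' Contextual cue at given trials
#'
#' Scalar cue stream: stationary bandits emit 1 on every trial; flip-flop
#' bandits emit -1 in even phases and +1 in odd phases (changing exactly
#' when the switching arm's mean changes); smooth bandits encode which arm
#' currently has the maximal mean, mapped linearly onto `[-1, 1]`
#' (for 3 arms: arm 1 -> -1, arm 2 -> 0, arm 3 -> 1).
#'
#' @inheritParams arm_means_at
#' @return Numeric vector of cues, one per trial.
#' @export
context_cue_at <- function(spec, t) {
  t <- check_trials(spec, t)
  switch(spec$kind,
    stationary = rep(1, length(t)),
    flipflop = {
      phase <- ((t - 1L) %/% spec$switch_period) %% 2L
      ifelse(phase == 0L, -1, 1)
    },
    smooth = {
      M <- arm_means_at(spec, t)
      if (is.null(dim(M))) M <- matrix(M, 1)
      best <- max.col(M, ties.method = "first")
      2 * (best - 1) / (spec$n_arms - 1) - 1
    })
}

#' Sample a Bernoulli reward
#'
#' Draws `r_t ~ Bernoulli(mu_a(t))` for the chosen arm, using R's global
#' RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @inheritParams arm_means_at
#' @param action chosen arm index (scalar `t` only).
#' @return 0 or 1.
#' @export
sample_reward <- function(spec, t, action) {
  stopifnot(length(t) == 1, length(action) == 1)
  if (action < 1 || action > spec$n_arms) {
    stop("invalid arm index: ", action, call. = FALSE)
  }
  mu <- arm_means_at(spec, t)[action]
  as.integer(stats::runif(1) < mu)
}

#' Full trial table of a bandit schedule
#'
#' @param spec a [bandit_spec()].
#' @param trials trial indices; defaults to `1:horizon`.
#' @return A tibble with columns `t`, `cue`, one `mu_<arm>` column per arm,
#'   and `best_arm`.
#' @export
bandit_schedule <- function(spec, trials = seq_len(spec$horizon)) {
  M <- arm_means_at(spec, trials)
  if (is.null(dim(M))) M <- matrix(M, 1)
  colnames(M) <- paste0("mu_", seq_len(spec$n_arms))
  dplyr::bind_cols(
    tibble::tibble(t = as.integer(trials), cue = context_cue_at(spec, trials)),
    tibble::as_tibble(M)) |>
    dplyr::mutate(best_arm = max.col(M, ties.method = "first"))
}

#' Cumulative pseudo-regret of an action sequence
#'
#' Computes the per-trial and cumulative pseudo-regret
#' \deqn{R_T = \sum_{t=1}^{T} \big(\max_i \mu_i(t) - \mu_{a_t}(t)\big),}
#' i.e. the expected (schedule-mean) shortfall of the chosen arm relative
#' to the instantaneous best arm, not the realised reward shortfall.
#'
#' @param actions integer vector of chosen arms covering trials
#'   `1..length(actions)` without gaps, or a data frame with columns `t`
#'   and `action`.
#' @param spec a [bandit_spec()].
#' @return A tibble with columns `t`, `action`, `regret_increment`,
#'   `cumulative_regret` (non-decreasing).
#' @export
cumulative_regret <- function(actions, spec) {
  if (is.data.frame(actions)) {
    ord <- order(actions$t)
    stopifnot(identical(as.integer(actions$t[ord]),
                        seq_along(actions$t)))
    actions <- actions$action[ord]
  }
  actions <- as.integer(actions)
  if (any(actions < 1 | actions > spec$n_arms)) {
    stop("invalid arm index in action sequence", call. = FALSE)
  }
  ts <- seq_along(actions)
  M <- arm_means_at(spec, ts)
  if (is.null(dim(M))) M <- matrix(M, 1)
  inc <- apply(M, 1, max) - M[cbind(ts, actions)]
  tibble::tibble(t = ts, action = actions, regret_increment = inc,
                 cumulative_regret = cumsum(inc))
}
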