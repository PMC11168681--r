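test_that("REINFORCE loss matches direct evaluation and its sign logic", {
  expect_equal(reinforce_loss(0.7, 0.7, 0.4), 0)
  expect_equal(reinforce_loss(0.5, 1, 0.5), -0.5 * log(0.5))
  expect_equal(round(reinforce_loss(0.5, 1, 0.5), 5), 0.34657)
  expect_warning(reinforce_loss(0.5, 1, 0), "clamped")
  # reward above the running mean pushes the selected logit up (negative
  # gradient of the minimised loss with respect to that logit)
  p <- policy_from_logits(c(0.3, -0.2, 0.1))$p
  a <- 2L
  gy <- (0.4 - 1) * ((seq_len(3) == a) - p)   # r = 1 > r_bar = 0.4
  expect_lt(gy[a], 0)
  gy2 <- (0.9 - 0) * ((seq_len(3) == a) - p)  # r = 0 < r_bar = 0.9
  expect_gt(gy2[a], 0)
})

test_that("the trace's running mean and loss are internally consistent", {
  spec <- bandit_spec("stationary", horizon = 120)
  run <- train_run(init_agent(n = 6, m = 3, seed = 1), spec, seed = 2)
  tr <- run$trace
  expect_equal(tr$reward_mean, cumsum(tr$reward) / seq_len(nrow(tr)),
               tolerance = 1e-12)
  expect_equal(tr$loss,
               (tr$reward_mean - tr$reward) * log(pmax(tr$p_selected, 1e-12)),
               tolerance = 1e-12)
  expect_true(all(diff(tr$cumulative_regret) >= 0))
})

test_that("zero learning rate leaves parameters untouched", {
  spec <- bandit_spec("stationary", horizon = 80)
  ag <- init_agent(n = 6, m = 3, seed = 5)
  before <- ag$params
  run <- train_run(ag, spec, lr = 0, seed = 6)
  expect_identical(run$agent$params, before)
})

test_that("identical configuration and seed reproduce the trace bitwise", {
  spec <- bandit_spec("flipflop", horizon = 150, switch_period = 50)
  r1 <- train_run(init_agent(n = 6, m = 3, seed = 7), spec, seed = 8)
  r2 <- train_run(init_agent(n = 6, m = 3, seed = 7), spec, seed = 8)
  expect_identical(r1$trace, r2$trace)
})

test_that("uniform play accrues regret at the analytic rate", {
  spec <- bandit_spec("stationary", horizon = 3000)
  ag <- init_agent(n = 4, m = 2, seed = 1)
  ag$params$W_out[] <- 0
  ag$params$b_out[] <- 0   # logits all zero -> uniform policy
  run <- train_run(ag, spec, lr = 0, seed = 2)
  rate <- run$trace$cumulative_regret[3000] / 3000
  expect_lt(abs(rate - (0.4 + 0 + 0.7) / 3), 0.02)
})

test_that("the trial loop is agnostic to the agent implementation", {
  # two mock agent classes with the same (uniform) policy must see exactly
  # the same environment draws and produce identical traces
  mock_step <- function(agent, cue) list(agent = agent, logits = c(0, 0, 0))
  mock_grad <- function(agent, gy) list()
  .S3method("agent_step", "mock_a", mock_step)
  .S3method("agent_gradients", "mock_a", mock_grad)
  .S3method("agent_step", "mock_b", mock_step)
  .S3method("agent_gradients", "mock_b", mock_grad)
  make_mock <- function(cls) {
    structure(list(n_actions = 3L, params = list(), state = NULL),
              class = c(cls, "bandit_agent"))
  }
  spec <- bandit_spec("flipflop", horizon = 200, switch_period = 50)
  ra <- train_run(make_mock("mock_a"), spec, seed = 9)
  rb <- train_run(make_mock("mock_b"), spec, seed = 9)
  expect_identical(ra$trace, rb$trace)
})

test_that("the time-scale ablation changes dynamics but not parameter counts", {
  counts <- vapply(c(1, 0.1, 0.01), function(tau) {
    ag <- make_agent("neuroastro", seed = 1, n = 8, m = 4, tau = tau)
    sum(vapply(ag$params, length, integer(1)))
  }, numeric(1))
  expect_equal(length(unique(counts)), 1L)
})

test_that("comparison and sweep drivers aggregate per run", {
  spec <- bandit_spec("stationary", horizon = 60)
  cmp <- run_comparison(c("ucb", "ts"), spec, runs = 2, seed = 1)
  expect_equal(nrow(cmp), 4L)
  g <- glance(cmp)
  expect_equal(sort(g$kind), c("ts", "ucb"))
  expect_true(all(g$runs == 2))
  one <- run_comparison("ucb", spec, runs = 1, seed = 1)
  expect_equal(glance(one)$sd_regret, NA_real_)

  sw <- ratio_sweep(c(0.25, 1), spec, n = 8, runs = 1, seed = 1,
                    agent_args = list())
  expect_equal(sw$m, c(2L, 8L))
})

test_that("flip-flop slope windows align with the phase starts", {
  spec <- bandit_spec("flipflop", horizon = 400, switch_period = 100)
  run <- train_run(make_agent("ucb", n_actions = 3), spec, seed = 3)
  sl <- flipflop_slopes(run, window = 50)
  expect_equal(sl$phase_start, c(1L, 101L, 201L, 301L))
  expect_true(all(sl$slope >= 0))
})
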