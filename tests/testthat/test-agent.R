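test_that("initialisation is seeded, sized and scaled as specified", {
  a1 <- init_agent(n = 8, m = 4, seed = 3)
  a2 <- init_agent(n = 8, m = 4, seed = 3)
  expect_identical(a1$params, a2$params)
  expect_equal(a1$state$x, rep(0, 8))
  expect_equal(a1$state$W, rep(0, 64))
  expect_equal(a1$state$z, rep(0, 4))

  default <- init_agent(seed = 1)
  expect_equal(default$n, 128L)
  expect_equal(default$m, 64L)
  expect_equal(dim(default$params$D), c(128^2, 64))
  expect_equal(dim(default$params$H), c(64, 128^2))

  # astrocyte coupling F has fan-in m = 64, so entry sd should be 1/8
  big <- init_agent(n = 8, m = 64, seed = 5)
  expect_lt(abs(sd(big$params$F) - 1 / 8) / (1 / 8), 0.2)
  # input maps are uniform within their fan-in bound
  expect_true(all(abs(big$params$W_in1) <= 1))
  expect_true(all(abs(big$params$W_out) <= 1 / sqrt(8)))
})

test_that("logits pass the readout bias through a silent network", {
  ag <- init_agent(n = 4, m = 2, seed = 1)
  ag$params$W_in1[] <- 0
  ag$params$W_out[] <- 0
  ag$params$b_out <- c(1, 2, 3)
  st <- agent_step(ag, cue = 1)
  expect_equal(st$logits, c(1, 2, 3))
})

test_that("one agent step equals the discrete-map step plus readout", {
  ag <- init_agent(n = 3, m = 2, seed = 6)
  cue <- -1
  st <- agent_step(ag, cue)
  manual <- euler_discrete_step(
    ag$state, C = ag$params$C, D = ag$params$D, Fmat = ag$params$F,
    H = ag$params$H, gamma = ag$gamma, tau = ag$tau,
    ext = list(x = as.numeric(ag$params$W_in1 %*% cue),
               z = as.numeric(ag$params$W_in2 %*% cue)))
  expect_equal(st$agent$state$x, manual$x)
  expect_equal(st$agent$state$W, manual$W)
  expect_equal(st$agent$state$z, manual$z)
  expect_equal(st$logits,
               as.numeric(ag$params$W_out %*% manual$x) + ag$params$b_out)
})

test_that("astrocyte updates obey the gamma*tau step-size bound", {
  ag <- init_agent(n = 6, m = 3, seed = 2)
  st <- agent_step(ag, cue = 1)
  bound <- ag$gamma * ag$tau *
    (0.25 * rowSums(abs(ag$params$H)) + abs(ag$params$W_in2 %*% 1))
  expect_true(all(abs(st$agent$state$z) <= bound + 1e-12))
})

test_that("softmax policy matches direct evaluation and is shift invariant", {
  expect_equal(policy_from_logits(c(0, 0, 0))$p, rep(1 / 3, 3))
  expect_equal(round(policy_from_logits(c(1, 0, 0))$p, 4),
               c(0.5761, 0.2119, 0.2119))
  p1 <- policy_from_logits(c(2, -1, 0.5))$p
  p2 <- policy_from_logits(c(2, -1, 0.5) + 123.4)$p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  big <- policy_from_logits(c(1000, 0, 0))$p  # overflow-safe
  expect_equal(big[1], 1)
})

test_that("action sampling is categorical, seeded and degenerate-safe", {
  expect_true(all(replicate(25, select_action(c(1, 0, 0))) == 1L))
  set.seed(10)
  draws <- replicate(3e4, select_action(rep(1 / 3, 3)))
  expect_true(all(abs(tabulate(draws, 3) / 3e4 - 1 / 3) < 0.02))
  set.seed(77); a <- select_action(c(0.2, 0.5, 0.3))
  set.seed(77); b <- select_action(c(0.2, 0.5, 0.3))
  expect_identical(a, b)
  expect_error(select_action(c(0.5, 0.2)), "probability")
})

test_that("analytic gradients match finite differences on a small instance", {
  # includes the windowed path through the plasticity and astrocyte maps
  ag <- init_agent(n = 4, m = 3, gamma = 0.3, tau = 0.5, bptt_window = 8,
                   seed = 7)
  expect_lt(fd_gradient_gap(ag, steps = 5), 1e-5)
  rnn <- init_stacked_agent("vanilla", units = 5, bptt_window = 8, seed = 7)
  expect_lt(fd_gradient_gap(rnn, steps = 5), 1e-5)
  lstm <- init_stacked_agent("lstm", units = 4, bptt_window = 8, seed = 7)
  expect_lt(fd_gradient_gap(lstm, steps = 5), 1e-5)
  gru <- init_stacked_agent("gru", units = 4, bptt_window = 8, seed = 7)
  expect_lt(fd_gradient_gap(gru, steps = 5), 1e-5)
})

test_that("with tau = 0.01 astrocytes move far slower than neurons", {
  set.seed(12)
  ag <- init_agent(n = 16, m = 8, tau = 0.01, seed = 13)
  dx <- 0; dz <- 0
  for (t in 1:100) {
    x0 <- ag$state$x; z0 <- ag$state$z
    st <- agent_step(ag, cue = sample(c(-1, 1), 1))
    ag <- st$agent
    dx <- dx + mean(abs(ag$state$x - x0))
    dz <- dz + mean(abs(ag$state$z - z0))
  }
  expect_lt(dz / dx, 0.2)
})

test_that("agent state stays bounded over a long untrained run", {
  spec <- bandit_spec("flipflop", horizon = 3000, switch_period = 750)
  run <- train_run(init_agent(n = 16, m = 8, seed = 4), spec, lr = 0,
                   seed = 5)
  expect_true(all(is.finite(run$agent$state$x)))
  expect_true(all(is.finite(run$agent$state$z)))
  expect_lt(max(abs(run$agent$state$x)), 100)
})

test_that("agent checkpoints round-trip through JSON", {
  ag <- init_agent(n = 5, m = 3, seed = 9)
  st <- agent_step(ag, 1)  # advance so the state is nontrivial
  path <- withr::local_tempfile(fileext = ".json")
  save_agent(st$agent, path)
  back <- load_agent(path)
  expect_equal(back$params, st$agent$params)
  expect_equal(back$state, st$agent$state)
  # identical next step from the restored agent
  s1 <- agent_step(st$agent, -1)
  s2 <- agent_step(back, -1)
  expect_equal(s1$logits, s2$logits)
})
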