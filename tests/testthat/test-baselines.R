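test_that("stacked recurrent agents pass structural identities", {
  ag <- init_stacked_agent("vanilla", units = 4, seed = 1)
  for (nm in setdiff(names(ag$params), "b_out")) ag$params[[nm]][] <- 0
  ag$params$b_out <- c(0.5, -1, 2)
  st <- agent_step(ag, cue = 1)
  expect_equal(st$logits, c(0.5, -1, 2))

  # identical seeds and inputs give identical trajectories
  spec <- bandit_spec("stationary", horizon = 50)
  r1 <- train_run(init_stacked_agent("gru", units = 6, seed = 2), spec,
                  seed = 3)
  r2 <- train_run(init_stacked_agent("gru", units = 6, seed = 2), spec,
                  seed = 3)
  expect_identical(r1$trace, r2$trace)

  # gate multiplicity orders the parameter counts at equal width
  count <- function(kind) {
    sum(vapply(init_stacked_agent(kind, units = 8, seed = 1)$params,
               length, integer(1)))
  }
  expect_gt(count("gru"), count("vanilla"))
  expect_gt(count("lstm"), count("gru"))
})

test_that("UCB1 forces unpulled arms then maximises the padded index", {
  pol <- ucb_policy(2)
  expect_equal(policy_select(pol, 1), 1L)
  pol <- policy_update(pol, 1L, 1)
  expect_equal(policy_select(pol, 2), 2L)

  # counts (10, 10), means (0.5, 0.9), t = 20: indices 1.274 vs 1.674
  pol <- ucb_policy(2)
  for (i in 1:10) pol <- policy_update(pol, 1L, as.numeric(i <= 5))
  for (i in 1:10) pol <- policy_update(pol, 2L, as.numeric(i <= 9))
  st <- gliabandit:::ucb_statistics(pol, 20)
  idx <- st$sums / st$counts + sqrt(2 * log(st$t_eff) / st$counts)
  expect_equal(idx, c(1.274, 1.674), tolerance = 1e-3)
  expect_equal(policy_select(pol, 20), 2L)

  # deterministic lowest-index tie-break
  pol2 <- ucb_policy(3)
  for (a in 1:3) for (i in 1:4) pol2 <- policy_update(pol2, a, 1)
  expect_equal(policy_select(pol2, 13), 1L)
})

test_that("Thompson sampling updates conjugately and exploits dominant arms", {
  pol <- ts_policy(2)
  pol <- policy_update(pol, 1L, 1)
  expect_equal(pol$alpha, c(2, 1))
  expect_equal(pol$beta, c(1, 1))
  pol$alpha <- c(100, 1); pol$beta <- c(1, 100)
  set.seed(6)
  picks <- replicate(1e4, policy_select(pol, 1))
  expect_gt(mean(picks == 1L), 0.99)
  set.seed(3); a <- policy_select(ts_policy(3), 1)
  set.seed(3); b <- policy_select(ts_policy(3), 1)
  expect_identical(a, b)
})

test_that("non-stationary UCB variants reduce to UCB1 in their limits", {
  set.seed(11)
  acts <- sample(1:3, 200, replace = TRUE)
  rews <- rbinom(200, 1, 0.5)
  u <- ucb_policy(3, "ucb1")
  d <- ucb_policy(3, "ducb", discount = 1)
  s <- ucb_policy(3, "swucb", window = 10000L)
  for (t in 1:200) {
    expect_equal(policy_select(d, t), policy_select(u, t))
    expect_equal(policy_select(s, t), policy_select(u, t))
    u <- policy_update(u, acts[t], rews[t])
    d <- policy_update(d, acts[t], rews[t])
    s <- policy_update(s, acts[t], rews[t])
  }
  expect_equal(d$counts, u$counts)
  expect_equal(s$counts, u$counts)
})

test_that("discounting forgets a flipped arm geometrically", {
  gamma_d <- 0.95
  pol <- ucb_policy(2, "ducb", discount = gamma_d)
  for (i in 1:200) pol <- policy_update(pol, 1L, 0)  # pre-flip: always 0
  gaps <- numeric(30)
  for (k in 1:30) {                                  # post-flip: always 1
    pol <- policy_update(pol, 1L, 1)
    gaps[k] <- 1 - pol$sums[1] / pol$counts[1]
  }
  # the residual gap to the new mean shrinks at rate ~gamma_d
  ratios <- gaps[-1] / gaps[-30]
  expect_true(all(abs(ratios - gamma_d) < 0.02))
})

test_that("sliding-window statistics drop observations beyond the window", {
  pol <- ucb_policy(2, "swucb", window = 5L)
  for (i in 1:5) pol <- policy_update(pol, 1L, 1)
  for (i in 1:5) pol <- policy_update(pol, 2L, 0)
  expect_equal(pol$counts, c(0, 5))
  expect_equal(pol$sums, c(0, 0))
})

test_that("UCB and TS regret rates decay on the stationary bandit", {
  spec <- bandit_spec("stationary", horizon = 5000)
  for (kind in c("ucb", "ts")) {
    run <- train_run(make_agent(kind), spec, seed = 14)
    inc <- run$trace$regret_increment
    expect_lt(mean(inc[4001:5000]), mean(inc[1:1000]))
  }
})
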