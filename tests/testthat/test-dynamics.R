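ref_params <- motif_params()  # bistable reference parameterisation

test_that("motif vector field reproduces the hand-computed origin value", {
  f0 <- motif_vector_field(motif_state(), ref_params)
  # at the origin phi = 0.5, psi(0) = 0: w-dot = c * 0.25 / tau2, z-dot = h * 0.25
  expect_equal(unname(f0), c(0, 0, 300, -250, 1.5), tolerance = 1e-12)
})

test_that("external drive enters each neuron equation linearly with gain 1/tau", {
  s <- motif_state(0.3, -0.2, 1, -1, 0.5)
  f0 <- motif_vector_field(s, ref_params, drive = c(0, 0, 0))
  f1 <- motif_vector_field(s, ref_params, drive = c(0.25, 0, 0))
  expect_equal(f1[["x1"]] - f0[["x1"]], 0.25 / ref_params$tau1)
  expect_equal(f1[-1], f0[-1])
})

test_that("the generic hypernetwork field reduces exactly to the motif", {
  set.seed(7)
  for (i in 1:100) {
    p <- motif_params(a1 = runif(1, 0.2, 2), a2 = runif(1, 0.2, 2),
                      b1 = runif(1, 0.5, 3), b2 = runif(1, 0.5, 3),
                      c1 = runif(1, -12, 12), c2 = runif(1, -12, 12),
                      d1 = runif(1, -5, 5), d2 = runif(1, -5, 5),
                      eps = runif(1, 0.2, 2), h = runif(1, -6, 6),
                      tau1 = runif(1, 0.005, 0.1), tau2 = runif(1, 0.1, 0.5),
                      tau3 = runif(1, 0.5, 2))
    s <- runif(5, -2, 2)
    drv <- runif(3, -1, 1)
    fm <- motif_vector_field(s, p, drv)
    np <- motif_as_network(p)
    fn <- full_vector_field(network_state(s[1:2], s[3:4], s[5]), np,
                            drive = list(u = drv[1:2], v = drv[3]))
    expect_lt(max(abs(c(fn$x, fn$W, fn$z) - unname(fm))), 1e-12)
  }
})

test_that("decoupled network decays to the origin componentwise", {
  np <- network_params(n = 3, m = 2,
                       synapse_index = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
                       a = c(1, 2, 3), h = rep(0, 2))
  f0 <- full_vector_field(network_state(rep(0, 3), rep(0, 3), rep(0, 2)), np)
  expect_equal(c(f0$x, f0$W, f0$z), rep(0, 8))
  x0 <- c(0.5, -1, 2)
  f1 <- full_vector_field(network_state(x0, rep(0, 3), rep(0, 2)), np)
  expect_equal(f1$x, -c(1, 2, 3) * x0 / np$tau_n)
})

test_that("network parameter validation rejects malformed wiring", {
  expect_error(network_params(n = 2, m = 1, synapse_index = rbind(c(1L, 1L))),
               "self-pairs")
  expect_error(network_params(n = 2, m = 1,
                              synapse_index = rbind(c(1L, 2L), c(1L, 2L))),
               "repeated")
  expect_error(network_params(n = 2, m = 1, synapse_index = rbind(c(1L, 3L))),
               "nonexistent")
  expect_error(network_params(n = 2, m = 1, synapse_index = rbind(c(1L, 2L)),
                              synapse_astro = 2L), "astrocyte")
  expect_error(network_params(n = 3, m = 2, synapse_index = rbind(c(1L, 2L))),
               "m <= o")
})

test_that("RK4 keeps an equilibrium fixed and converges under step halving", {
  eq <- find_fixed_points(ref_params, n_starts = 150)
  stable <- Filter(function(e) e$classification == "stable", eq$equilibria)
  s0 <- stable[[1]]$state
  traj <- simulate_motif(ref_params, s0, t_end = 1, record_every = 200L)
  drift <- max(abs(as.matrix(traj[nrow(traj), -1]) - rep(s0, each = 1)))
  expect_lt(drift, 1e-9)

  init <- motif_state(0.5, -0.5, 1, 1, 0.2)
  a <- simulate_motif(ref_params, init, t_end = 10, dt = 5e-4,
                      record_every = 10000L)
  b <- simulate_motif(ref_params, init, t_end = 10, dt = 2.5e-4,
                      record_every = 20000L)
  expect_lt(max(abs(as.matrix(a[nrow(a), -1]) - as.matrix(b[nrow(b), -1]))),
            1e-6)
})

test_that("in-package RK4 agrees with an independent adaptive integrator", {
  init <- motif_state(1, -1, 2, -2, 0.5)
  mine <- simulate_motif(ref_params, init, t_end = 5, dt = 5e-4,
                         record_every = 10000L)
  f_desolve <- function(t, y, parms) {
    list(unname(motif_vector_field(y, ref_params)))
  }
  ref <- deSolve::ode(y = as.numeric(init), times = c(0, 5), func = f_desolve,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  expect_equal(as.numeric(mine[nrow(mine), -1]),
               as.numeric(ref[nrow(ref), -1]), tolerance = 1e-6)
})

test_that("trajectories from a wide box stay inside a fixed bound", {
  # numeric surrogate for the asymptotic-boundedness of the motif flow
  set.seed(1)
  inits <- matrix(runif(5 * 50, -5, 5), nrow = 5)
  worst <- 0
  p <- ref_params
  act <- p$activations
  f <- function(t, y) {
    p1 <- act$phi(y[1, ]); p2 <- act$phi(y[2, ]); pz <- act$psi(y[5, ])
    corr <- p1 * p2
    rbind((-p$a1 * y[1, ] + y[4, ] * p2) / p$tau1,
          (-p$a2 * y[2, ] + y[3, ] * p1) / p$tau1,
          (-p$b1 * y[3, ] + p$c1 * corr + p$d1 * pz) / p$tau2,
          (-p$b2 * y[4, ] + p$c2 * corr + p$d2 * pz) / p$tau2,
          (-p$eps * y[5, ] + p$h * corr) / p$tau3)
  }
  out <- gliabandit:::rk4_integrate(f, inits, t_end = 100, dt = 1e-3,
                                    record_every = .Machine$integer.max,
                                    monitor = function(t, y) {
                                      worst <<- max(worst, max(abs(y)))
                                    })
  expect_lt(worst, 50)
})

test_that("astrocyte activity changes an order of magnitude slower than neurons", {
  # the fast subsystem settles within ~5 tau1 while z drifts throughout, so
  # compare peak rates of change along the transient
  traj <- simulate_motif(ref_params, motif_state(1.5, -1, 0, 0, 0),
                         t_end = 0.5, dt = 5e-4, record_every = 10L)
  d <- apply(as.matrix(traj[, -1]), 2, diff)
  dt_rec <- diff(traj$t)
  rate <- apply(abs(d / dt_rec), 2, max)
  expect_lt(rate[["z"]] * 10, max(rate[["x1"]], rate[["x2"]]))
})

test_that("a too-coarse step triggers the accuracy warning", {
  expect_warning(simulate_motif(ref_params, motif_state(0.1, 0, 0, 0, 0),
                                t_end = 0.05, dt = 0.005),
                 "tau_min/10")
})
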