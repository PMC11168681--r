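# Independent oracles used by the unit tests. These deliberately avoid the
# package's Newton/Jacobian machinery: root finding is nested 1-D scanning
# with uniroot, and derivatives are central finite differences.

# Equilibria of the frozen-astrocyte reduced motif via the 1-D
# self-consistency reduction: at equilibrium w1, w2 are explicit functions
# of (x1, x2); x2 is solved from its own balance by bracket scanning for
# each x1, and the remaining scalar x1 balance is scanned for sign changes.
oracle_reduced_equilibria_x1 <- function(params, theta,
                                         outer_grid = seq(-12, 12,
                                                          length.out = 961),
                                         inner_range = c(-12, 12)) {
  p <- params
  phi <- p$activations$phi
  w_eq <- function(x1, x2) {
    corr <- phi(x1) * phi(x2)
    c(w1 = (p$c1 * corr + p$d1 * theta) / p$b1,
      w2 = (p$c2 * corr + p$d2 * theta) / p$b2)
  }
  g1 <- function(x1, x2) -p$a1 * x1 + w_eq(x1, x2)[["w2"]] * phi(x2)
  g2 <- function(x1, x2) -p$a2 * x2 + w_eq(x1, x2)[["w1"]] * phi(x1)

  # scan `outer` over its grid; at each value solve `inner_fn = 0` for the
  # other coordinate by bracket scanning, then look for sign changes of
  # `resid_fn` along each inner-root branch and bisect on the outer axis.
  scan_one_way <- function(inner_fn, resid_fn, report) {
    inner_roots_at <- function(v) {
      grid <- seq(inner_range[1], inner_range[2], length.out = 481)
      vals <- vapply(grid, function(w) inner_fn(v, w), numeric(1))
      roots <- numeric(0)
      for (i in seq_len(length(grid) - 1)) {
        if (vals[i] == 0) roots <- c(roots, grid[i])
        else if (vals[i] * vals[i + 1] < 0) {
          roots <- c(roots, stats::uniroot(function(w) inner_fn(v, w),
                                           c(grid[i], grid[i + 1]),
                                           tol = 1e-13)$root)
        }
      }
      roots
    }
    found <- matrix(numeric(0), 0, 2)
    prev <- NULL
    for (v in outer_grid) {
      ws <- inner_roots_at(v)
      cur <- lapply(ws, function(w) list(w = w, f = resid_fn(v, w)))
      if (!is.null(prev) && length(prev$branches)) {
        for (cc in cur) {
          d <- vapply(prev$branches, function(b) abs(b$w - cc$w), numeric(1))
          b <- prev$branches[[which.min(d)]]
          if (min(d) < 0.5 && is.finite(b$f) && b$f * cc$f < 0) {
            lo <- prev$v; hi <- v
            flo <- b$f
            w_ref <- (b$w + cc$w) / 2
            for (it in 1:60) {
              mid <- (lo + hi) / 2
              wr <- inner_roots_at(mid)
              if (!length(wr)) break
              wv <- wr[which.min(abs(wr - w_ref))]
              fm <- resid_fn(mid, wv)
              if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
              if (hi - lo < 1e-11) break
            }
            mid <- (lo + hi) / 2
            wr <- inner_roots_at(mid)
            wv <- wr[which.min(abs(wr - w_ref))]
            found <- rbind(found, report(mid, wv))
          }
        }
      }
      prev <- list(v = v, branches = cur)
    }
    found
  }
  # parameterise by x1 (inner solve for x2) and by x2 (inner solve for x1):
  # a root sitting at a fold of one parameterisation is regular in the other
  roots <- rbind(
    scan_one_way(function(x1, x2) g2(x1, x2),
                 function(x1, x2) g1(x1, x2),
                 function(x1, x2) c(x1, x2)),
    scan_one_way(function(x2, x1) g1(x1, x2),
                 function(x2, x1) g2(x1, x2),
                 function(x2, x1) c(x1, x2)))
  if (!nrow(roots)) return(numeric(0))
  x1s <- sort(roots[, 1])
  x1s[c(TRUE, diff(x1s) > 1e-5)]
}

# central finite-difference Jacobian of a vector field
oracle_fd_jacobian <- function(f, x, h = 1e-6) {
  n_out <- length(f(x))
  J <- matrix(0, n_out, length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# finite-difference check of agent gradients: returns worst absolute
# discrepancy across sampled parameter entries
fd_gradient_gap <- function(agent0, steps = 5, eps = 1e-6,
                            entries_per_param = 5) {
  cues <- sin(seq_len(steps))
  fwd <- function(agent) {
    st <- NULL
    for (t in seq_len(steps)) {
      st <- agent_step(agent, cues[t])
      agent <- st$agent
    }
    list(agent = agent, logits = st$logits)
  }
  out <- fwd(agent0)
  p <- policy_from_logits(out$logits)$p
  a <- 2L
  adv <- 0.7
  gy <- adv * ((seq_along(p) == a) - p)
  gr <- agent_gradients(out$agent, gy)
  loss_of <- function(params) {
    ag <- agent0
    ag$params <- params
    o <- fwd(ag)
    adv * log(policy_from_logits(o$logits)$p[a])
  }
  worst <- 0
  for (nm in names(agent0$params)) {
    len <- length(agent0$params[[nm]])
    for (k in unique(round(seq(1, len, length.out = entries_per_param)))) {
      pp <- agent0$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- agent0$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      worst <- max(worst, abs(fd - gr[[nm]][k]))
    }
  }
  worst
}
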