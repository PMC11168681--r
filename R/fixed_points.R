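#' Analytic Jacobian of the motif vector field
#'
#' Uses the closed-form derivatives of the default activations
#' (`phi' = phi (1 - phi)`, `psi' = 1 - psi^2`; general activations fall
#' back to finite differences inside [activation_triple()]). Rows are
#' scaled by the corresponding `1/tau`, matching [motif_vector_field()].
#'
#' @param state a [motif_state()] (order `x1, x2, w1, w2, z`).
#' @param params a [motif_params()].
#' @return A 5 x 5 numeric matrix.
#' @export
motif_jacobian <- function(state, params) {
  if (!all(is.finite(state))) stop("non-finite motif state", call. = FALSE)
  p <- params
  act <- p$activations
  s <- as.numeric(state)
  p1 <- act$phi(s[1]); p2 <- act$phi(s[2])
  dp1 <- act$dphi(s[1]); dp2 <- act$dphi(s[2])
  dpz <- act$dpsi(s[5])
  J <- matrix(0, 5, 5)
  J[1, ] <- c(-p$a1, s[4] * dp2, 0, p2, 0) / p$tau1
  J[2, ] <- c(s[3] * dp1, -p$a2, p1, 0, 0) / p$tau1
  J[3, ] <- c(p$c1 * dp1 * p2, p$c1 * p1 * dp2, -p$b1, 0, p$d1 * dpz) / p$tau2
  J[4, ] <- c(p$c2 * dp1 * p2, p$c2 * p1 * dp2, 0, -p$b2, p$d2 * dpz) / p$tau2
  J[5, ] <- c(p$h * dp1 * p2, p$h * p1 * dp2, 0, 0, -p$eps) / p$tau3
  J
}

# Jacobian of the reduced (frozen astrocyte output) 4-ODE subsystem
reduced_jacobian <- function(state4, params) {
  p <- params
  act <- p$activations
  s <- as.numeric(state4)
  p1 <- act$phi(s[1]); p2 <- act$phi(s[2])
  dp1 <- act$dphi(s[1]); dp2 <- act$dphi(s[2])
  J <- matrix(0, 4, 4)
  J[1, ] <- c(-p$a1, s[4] * dp2, 0, p2) / p$tau1
  J[2, ] <- c(s[3] * dp1, -p$a2, p1, 0) / p$tau1
  J[3, ] <- c(p$c1 * dp1 * p2, p$c1 * p1 * dp2, -p$b1, 0) / p$tau2
  J[4, ] <- c(p$c2 * dp1 * p2, p$c2 * p1 * dp2, 0, -p$b2) / p$tau2
  J
}

# Reduced vector field with frozen astrocyte output theta = psi(z)
reduced_vector_field <- function(state4, params, theta, drive = c(0, 0)) {
  p <- params
  act <- p$activations
  s <- as.numeric(state4)
  p1 <- act$phi(s[1]); p2 <- act$phi(s[2])
  corr <- p1 * p2
  c((-p$a1 * s[1] + s[4] * p2 + drive[[1]]) / p$tau1,
    (-p$a2 * s[2] + s[3] * p1 + drive[[2]]) / p$tau1,
    (-p$b1 * s[3] + p$c1 * corr + p$d1 * theta) / p$tau2,
    (-p$b2 * s[4] + p$c2 * corr + p$d2 * theta) / p$tau2)
}

#' Classify the stability of an equilibrium from its spectrum
#'
#' `stable` if every eigenvalue real part is below `-tol`, `unstable` if
#' any exceeds `+tol`, otherwise `nonhyperbolic` (reported, never silently
#' coerced).
#'
#' @param eigenvalues complex vector.
#' @param tol classification band on real parts (default `1e-8`).
#' @return `"stable"`, `"unstable"` or `"nonhyperbolic"`.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "nonhyperbolic"
}

# ---- multistart Newton machinery -------------------------------------------

# radical-inverse Halton sequence (deterministic low-discrepancy points)
halton_seq <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  stopifnot(dim <= length(primes))
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    for (i in seq_len(n)) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, d] <- r
    }
  }
  out
}

# damped Newton iteration on f with analytic Jacobian jac
newton_root <- function(f, jac, x0, tol = 1e-11, max_iter = 60) {
  x <- x0
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    nf <- max(abs(fx))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) return(x)
    J <- jac(x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      f_new <- f(x_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < nf) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { # accept full step as last resort
        x_new <- x - step
        f_new <- f(x_new)
        break
      }
    }
    x <- x_new
    fx <- f_new
  }
  if (all(is.finite(fx)) && max(abs(fx)) < 1e-8) x else NULL
}

# multistart + dedupe; returns matrix of roots (rows)
multistart_roots <- function(f, jac, box, n_starts, dedupe_tol = 1e-6,
                             extra_starts = NULL) {
  dim <- nrow(box)
  pts <- halton_seq(n_starts, dim)
  starts <- sweep(sweep(pts, 2, box[, 2] - box[, 1], "*"), 2, box[, 1], "+")
  if (!is.null(extra_starts) && length(extra_starts)) {
    starts <- rbind(do.call(rbind, extra_starts), starts)
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(f, jac, starts[i, ])
    if (is.null(r)) next
    dup <- FALSE
    for (q in roots) {
      if (max(abs(q - r)) < dedupe_tol) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (!length(roots)) matrix(numeric(0), 0, dim) else do.call(rbind, roots)
}

default_motif_box <- function() {
  # x and z boxes sized to the activation range; w equilibria scale as |c|/b
  rbind(x1 = c(-3, 3), x2 = c(-3, 3), w1 = c(-20, 20), w2 = c(-20, 20),
        z = c(-3, 3))
}

#' Locate all equilibria of the motif
#'
#' Multistart damped-Newton root finding from a deterministic
#' low-discrepancy (Halton) grid over `search_box`, with duplicates merged
#' at `dedupe_tol` in max-norm. Each root is returned with its residual,
#' Jacobian spectrum and stability classification.
#'
#' @param params a [motif_params()].
#' @param drive constant drive `(u1, u2, v)`; default zero.
#' @param search_box 5 x 2 matrix of per-dimension start intervals
#'   (rows `x1, x2, w1, w2, z`).
#' @param n_starts number of Halton start points (>= 100 recommended).
#' @param dedupe_tol max-norm tolerance for merging duplicate roots.
#' @param tol classification band for [classify_stability()].
#' @return An object of class `motif_equilibria`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @examples
#' eq <- find_fixed_points(motif_params(), n_starts = 120)
#' generics::glance(eq)
#' @export
find_fixed_points <- function(params, drive = c(0, 0, 0),
                              search_box = default_motif_box(),
                              n_starts = 200, dedupe_tol = 1e-6, tol = 1e-8) {
  f <- function(s) unname(motif_vector_field(s, params, drive))
  jac <- function(s) motif_jacobian(s, params)
  roots <- multistart_roots(f, jac, search_box, n_starts, dedupe_tol)
  eqs <- equilibria_from_roots(roots, f, jac, tol,
                               c("x1", "x2", "w1", "w2", "z"))
  structure(list(equilibria = eqs, params = params, drive = drive,
                 n_starts = n_starts, dedupe_tol = dedupe_tol),
            class = "motif_equilibria")
}

#' Equilibria of the frozen-astrocyte reduced subsystem
#'
#' Treats the astrocyte output as a fixed parameter `theta = psi(z)` in
#' `[-1, 1]` (singular-perturbation view: the astrocyte is slow relative to
#' neurons and synapses) and solves the remaining 4-ODE subsystem, in which
#' the meta-plastic drives become `d1 * theta` and `d2 * theta`.
#'
#' @inheritParams find_fixed_points
#' @param theta frozen astrocyte output, in `[-1, 1]`.
#' @param extra_starts optional list of length-4 warm-start vectors.
#' @return An object of class `motif_equilibria` (4-component states).
#' @export
reduced_fixed_points <- function(params, theta, drive = c(0, 0),
                                 search_box = default_motif_box()[1:4, ],
                                 n_starts = 200, dedupe_tol = 1e-6,
                                 tol = 1e-8, extra_starts = NULL) {
  if (!is.finite(theta) || abs(theta) > 1) {
    stop("theta must lie in [-1, 1]", call. = FALSE)
  }
  f <- function(s) reduced_vector_field(s, params, theta, drive)
  jac <- function(s) reduced_jacobian(s, params)
  roots <- multistart_roots(f, jac, search_box, n_starts, dedupe_tol,
                            extra_starts = extra_starts)
  eqs <- equilibria_from_roots(roots, f, jac, tol,
                               c("x1", "x2", "w1", "w2"))
  structure(list(equilibria = eqs, params = params, theta = theta),
            class = "motif_equilibria")
}

equilibria_from_roots <- function(roots, f, jac, tol, dim_names) {
  eqs <- lapply(seq_len(nrow(roots)), function(i) {
    s <- roots[i, ]
    names(s) <- dim_names
    ev <- eigen(jac(s), only.values = TRUE)$values
    list(state = s, residual = max(abs(f(s))), eigenvalues = ev,
         classification = classify_stability(ev, tol))
  })
  ord <- order(vapply(eqs, function(e) e$state[[1]], numeric(1)))
  eqs[ord]
}

#' @export
print.motif_equilibria <- function(x, ...) {
  n <- length(x$equilibria)
  cls <- vapply(x$equilibria, `[[`, character(1), "classification")
  cat(sprintf("<motif_equilibria> %d equilibri%s (%s)\n", n,
              if (n == 1) "um" else "a",
              if (n) paste(cls, collapse = ", ") else "none found"))
  if (n) print(tidy.motif_equilibria(x))
  invisible(x)
}

#' Tidy motif equilibria into a tibble
#'
#' @param x a `motif_equilibria` object.
#' @param ... unused.
#' @return One row per equilibrium: state coordinates, `residual`,
#'   `max_re_eig` (largest eigenvalue real part) and `classification`.
#' @export
tidy.motif_equilibria <- function(x, ...) {
  if (!length(x$equilibria)) {
    return(tibble::tibble(x1 = numeric(0), residual = numeric(0),
                          max_re_eig = numeric(0),
                          classification = character(0)))
  }
  states <- do.call(rbind, lapply(x$equilibria, function(e) e$state))
  dplyr::bind_cols(
    tibble::as_tibble(states),
    tibble::tibble(
      residual = vapply(x$equilibria, `[[`, numeric(1), "residual"),
      max_re_eig = vapply(x$equilibria,
                          function(e) max(Re(e$eigenvalues)), numeric(1)),
      classification = vapply(x$equilibria, `[[`, character(1),
                              "classification")))
}

#' One-line summary of motif equilibria
#'
#' @param x a `motif_equilibria` object.
#' @param ... unused.
#' @return A one-row tibble with counts by classification.
#' @export
glance.motif_equilibria <- function(x, ...) {
  cls <- vapply(x$equilibria, `[[`, character(1), "classification")
  tibble::tibble(n_equilibria = length(cls),
                 n_stable = sum(cls == "stable"),
                 n_unstable = sum(cls == "unstable"),
                 n_nonhyperbolic = sum(cls == "nonhyperbolic"))
}

#' Pseudo-bifurcation sweep over the frozen astrocyte output
#'
#' Sweeps `theta = psi(z)` across a grid, solving the reduced subsystem at
#' each value (warm-started from the neighbouring grid point plus fresh
#' Halton starts), links equilibria into branches by continuity in `x1`,
#' and localises any fold (count change) by bisection.
#'
#' @inheritParams reduced_fixed_points
#' @param theta_grid increasing grid in `[-1, 1]`; a spacing of 0.01 or
#'   finer is recommended.
#' @param n_starts fresh Halton starts per grid point.
#' @param fold_tol bisection width for fold localisation.
#' @return An object of class `bifurcation_sweep` with a `branches` tibble
#'   (`theta, branch_id, x1, x2, w1, w2, stability`) and a `folds` tibble
#'   (`theta_lo, theta_hi, count_lo, count_hi`).
#' @examples
#' bd <- bifurcation_sweep(motif_params(),
#'                         theta_grid = seq(-1, 1, by = 0.05),
#'                         n_starts = 60)
#' bd$folds
#' @export
bifurcation_sweep <- function(params, theta_grid = seq(-1, 1, by = 0.01),
                              n_starts = 80, dedupe_tol = 1e-6,
                              tol = 1e-8, fold_tol = 1e-4) {
  stopifnot(all(diff(theta_grid) > 0), all(abs(theta_grid) <= 1))
  solve_at <- function(theta, warm) {
    reduced_fixed_points(params, theta, n_starts = n_starts,
                         dedupe_tol = dedupe_tol, tol = tol,
                         extra_starts = warm)
  }
  rows <- list()
  counts <- integer(length(theta_grid))
  warm <- NULL
  branch_heads <- list()   # branch_id -> last x1
  next_branch <- 1L
  for (g in seq_along(theta_grid)) {
    th <- theta_grid[g]
    res <- solve_at(th, warm)
    eqs <- res$equilibria
    counts[g] <- length(eqs)
    warm <- lapply(eqs, function(e) unname(e$state))
    # link to existing branches greedily by x1 proximity
    assigned <- rep(NA_integer_, length(eqs))
    if (length(branch_heads) && length(eqs)) {
      open_ids <- as.integer(names(branch_heads))
      dist <- outer(vapply(eqs, function(e) e$state[["x1"]], numeric(1)),
                    unlist(branch_heads), function(a, b) abs(a - b))
      while (any(is.finite(dist))) {
        k <- arrayInd(which.min(dist), dim(dist))
        if (!is.finite(dist[k[1], k[2]])) break
        assigned[k[1]] <- open_ids[k[2]]
        dist[k[1], ] <- Inf
        dist[, k[2]] <- Inf
      }
    }
    new_heads <- list()
    for (i in seq_along(eqs)) {
      if (is.na(assigned[i])) {
        assigned[i] <- next_branch
        next_branch <- next_branch + 1L
      }
      e <- eqs[[i]]
      new_heads[[as.character(assigned[i])]] <- e$state[["x1"]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        theta = th, branch_id = assigned[i],
        x1 = e$state[["x1"]], x2 = e$state[["x2"]],
        w1 = e$state[["w1"]], w2 = e$state[["w2"]],
        stability = e$classification)
    }
    branch_heads <- new_heads
  }
  branches <- dplyr::bind_rows(rows)
  # localise folds where the equilibrium count changes between grid points
  folds <- list()
  count_at <- function(theta, warm) {
    length(solve_at(theta, warm)$equilibria)
  }
  for (g in seq_len(length(theta_grid) - 1)) {
    if (counts[g] != counts[g + 1]) {
      lo <- theta_grid[g]; hi <- theta_grid[g + 1]
      c_lo <- counts[g]; c_hi <- counts[g + 1]
      warm_b <- NULL
      while (hi - lo > fold_tol) {
        mid <- (lo + hi) / 2
        c_mid <- count_at(mid, warm_b)
        if (c_mid == c_lo) lo <- mid else hi <- mid
      }
      folds[[length(folds) + 1]] <- tibble::tibble(
        theta_lo = lo, theta_hi = hi, count_lo = c_lo, count_hi = c_hi)
    }
  }
  folds <- if (length(folds)) dplyr::bind_rows(folds) else {
    tibble::tibble(theta_lo = numeric(0), theta_hi = numeric(0),
                   count_lo = integer(0), count_hi = integer(0))
  }
  structure(list(branches = branches, folds = folds, counts = counts,
                 theta_grid = theta_grid, params = params),
            class = "bifurcation_sweep")
}

#' @export
print.bifurcation_sweep <- function(x, ...) {
  cat(sprintf("<bifurcation_sweep> %d grid points in [%g, %g]\n",
              length(x$theta_grid), min(x$theta_grid), max(x$theta_grid)))
  if (nrow(x$folds)) {
    for (i in seq_len(nrow(x$folds))) {
      cat(sprintf("  fold: count %d -> %d in theta (%.5f, %.5f)\n",
                  x$folds$count_lo[i], x$folds$count_hi[i],
                  x$folds$theta_lo[i], x$folds$theta_hi[i]))
    }
  } else {
    cat("  no fold in range\n")
  }
  invisible(x)
}

#' @export
tidy.bifurcation_sweep <- function(x, ...) x$branches

#' Plot a pseudo-bifurcation diagram
#'
#' @param object a [bifurcation_sweep()] result.
#' @param ... unused.
#' @return A ggplot: equilibrium `x1` against `theta`, solid for stable
#'   branches, dashed for unstable.
#' @export
autoplot.bifurcation_sweep <- function(object, ...) {
  br <- object$branches
  ggplot2::ggplot(br, ggplot2::aes(x = .data$theta, y = .data$x1,
                                   group = .data$branch_id,
                                   colour = .data$stability,
                                   linetype = .data$stability)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(stable = "solid", unstable = "dashed",
                 nonhyperbolic = "dotted")) +
    ggplot2::labs(x = expression(psi(z)), y = expression(x[1]),
                  title = "Equilibria of the frozen-astrocyte subsystem") +
    ggplot2::theme_minimal()
}
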