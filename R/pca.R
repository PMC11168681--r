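#' Principal-component projection of astrocyte and synaptic activity
#'
#' Centres each snapshot series and fits principal axes separately for the
#' astrocyte states `z_t` and the flattened synaptic weights `W_t`, then
#' projects every snapshot. Used to visualise how learning carves
#' context-specific synaptic trajectories while the astrocyte output moves
#' far less — the population-level signature of slow astrocytic
#' meta-plasticity.
#'
#' @param z matrix of astrocyte snapshots (rows = snapshots, columns =
#'   astrocytes), e.g. `run$snapshots$z` from [train_run()].
#' @param W matrix of flattened synaptic-weight snapshots.
#' @param contexts vector of per-snapshot context labels (e.g. the cue).
#' @param n_components principal components to retain (default 2).
#' @return An object of class `activity_projection` with per-series scores,
#'   singular values and loadings; see `tidy()` and `glance()` methods.
#' @export
pca_projection <- function(z, W, contexts = NULL, n_components = 2L) {
  z <- as.matrix(z); W <- as.matrix(W)
  stopifnot(nrow(z) == nrow(W), nrow(z) >= 2)
  if (is.null(contexts)) contexts <- rep(1, nrow(z))
  stopifnot(length(contexts) == nrow(z))
  fit_one <- function(M) {
    k <- min(n_components, ncol(M), nrow(M) - 1L)
    if (all(abs(sweep(M, 2, colMeans(M))) < 1e-300)) {
      warning("constant snapshot series: projection defined as zeros",
              call. = FALSE)
      return(list(scores = matrix(0, nrow(M), k), sdev = rep(0, k),
                  rotation = matrix(0, ncol(M), k)))
    }
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = k)
    list(scores = pc$x, sdev = pc$sdev[seq_len(k)], rotation = pc$rotation)
  }
  structure(list(z = fit_one(z), w = fit_one(W),
                 contexts = contexts, n_snapshots = nrow(z)),
            class = "activity_projection")
}

#' @export
print.activity_projection <- function(x, ...) {
  cat(sprintf("<activity_projection> %d snapshots, %d contexts\n",
              x$n_snapshots, length(unique(x$contexts))))
  print(glance.activity_projection(x))
  invisible(x)
}

#' @export
tidy.activity_projection <- function(x, ...) {
  one <- function(fit, series) {
    sc <- fit$scores
    tibble::tibble(snapshot = seq_len(nrow(sc)), series = series,
                   pc1 = sc[, 1],
                   pc2 = if (ncol(sc) >= 2) sc[, 2] else 0,
                   context = x$contexts)
  }
  dplyr::bind_rows(one(x$z, "astrocyte"), one(x$w, "synapse"))
}

#' Summary statistics of an activity projection
#'
#' For each series the score matrix is normalised to unit total variance
#' and the variance remaining *within* contexts is reported
#' (context-mean-weighted); a small within-context share means the series
#' separates the contexts cleanly and barely moves inside each. Also
#' reports the mean sign of the second astrocyte component per context.
#'
#' @param x an [pca_projection()] result.
#' @param ... unused.
#' @return A one-row tibble: `z_within_var`, `w_within_var`,
#'   `z_pc2_sign_flip` (TRUE if the mean second astrocyte component
#'   changes sign across contexts).
#' @export
glance.activity_projection <- function(x, ...) {
  within_var <- function(fit) {
    sc <- fit$scores
    tot <- sum(apply(sc, 2, stats::var))
    if (tot <= 0) return(0)
    sc <- sc / sqrt(tot)
    ctx <- split(seq_len(nrow(sc)), x$contexts)
    w <- vapply(ctx, function(idx) {
      if (length(idx) < 2) return(0)
      sum(apply(sc[idx, , drop = FALSE], 2, stats::var)) *
        length(idx) / nrow(sc)
    }, numeric(1))
    sum(w)
  }
  pc2_signs <- if (ncol(x$z$scores) >= 2) {
    tapply(x$z$scores[, 2], x$contexts, mean)
  } else 0
  tibble::tibble(z_within_var = within_var(x$z),
                 w_within_var = within_var(x$w),
                 z_pc2_sign_flip = length(pc2_signs) > 1 &&
                   max(pc2_signs) > 0 && min(pc2_signs) < 0)
}

#' Plot astrocyte and synaptic activity projections
#'
#' @param object an [pca_projection()] result.
#' @param ... unused.
#' @return A ggplot of the first two principal components per series,
#'   coloured by context.
#' @export
autoplot.activity_projection <- function(object, ...) {
  df <- tidy.activity_projection(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = factor(.data$context))) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free") +
    ggplot2::labs(colour = "context", x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
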