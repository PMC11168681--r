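#' Adam optimiser state
#'
#' Standard Adam with bias-corrected first and second moments, operating on
#' an arbitrary named list of numeric arrays.
#'
#' @param params named list of numeric vectors/matrices (a template; only
#'   shapes are used).
#' @param lr learning rate (default 0.001, the conventional default).
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param eps numerical stabiliser.
#' @return An object of class `adam_optimizer`.
#' @export
adam_optimizer <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  zeros <- lapply(params, function(x) x * 0)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 m = zeros, v = zeros, t = 0L),
            class = "adam_optimizer")
}

#' One Adam update
#'
#' @param opt an [adam_optimizer()].
#' @param params named list of current parameter arrays.
#' @param grads named list of gradients (same shapes as `params`).
#' @return A list with the updated `params` and `opt`.
#' @export
adam_update <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * gr
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}
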