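#' Parameters of the two-neuron / one-astrocyte motif
#'
#' The motif couples a reciprocal excitatory-inhibitory neuron pair
#' (`x1`, `x2`) through two plastic synapses (`w1`, `w2`) enveloped by a
#' single astrocyte (`z`), as five ODEs:
#' \deqn{\tau_1 \dot x_1 = -a_1 x_1 + w_2 \phi(x_2) + u_1}
#' \deqn{\tau_1 \dot x_2 = -a_2 x_2 + w_1 \phi(x_1) + u_2}
#' \deqn{\tau_2 \dot w_1 = -b_1 w_1 + c_1 \phi(x_1)\phi(x_2) + d_1 \psi(z)}
#' \deqn{\tau_2 \dot w_2 = -b_2 w_2 + c_2 \phi(x_1)\phi(x_2) + d_2 \psi(z)}
#' \deqn{\tau_3 \dot z = -\epsilon z + h \phi(x_1)\phi(x_2) + v}
#'
#' The defaults are a reference parameterisation in which the slow astrocyte
#' (`tau3 = 100 * tau1`) drives the fast neuron-synapse subsystem across a
#' saddle-node fold, producing two stable equilibria and one unstable one.
#'
#' @param a1,a2 neuron self-decay rates (> 0, 1/time).
#' @param b1,b2 synapse self-decay rates (> 0).
#' @param c1,c2 Hebbian gains (signed; negative = anti-Hebbian).
#' @param d1,d2 astrocyte-to-synapse meta-plasticity gains (signed).
#' @param eps astrocyte self-decay rate (> 0).
#' @param h astrocyte sensitivity to the pairwise firing correlation.
#' @param tau1,tau2,tau3 time constants of neurons, synapses, astrocyte
#'   (> 0; larger is slower).
#' @param activations an [activation_triple()].
#'
#' @return An object of class `motif_params`.
#' @examples
#' p <- motif_params()
#' motif_vector_field(motif_state(), p)
#' @export
motif_params <- function(a1 = 0.7, a2 = 0.6, b1 = 1.6, b2 = 1.7,
                         c1 = 12, c2 = -10, d1 = -4, d2 = 5,
                         eps = 0.6, h = 6,
                         tau1 = 0.01, tau2 = 0.01, tau3 = 1,
                         activations = activation_triple()) {
  vals <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
               d1 = d1, d2 = d2, eps = eps, h = h,
               tau1 = tau1, tau2 = tau2, tau3 = tau3)
  num_ok <- vapply(vals, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                   logical(1))
  if (!all(num_ok)) {
    stop("motif parameters must be finite scalars: ",
         paste(names(vals)[!num_ok], collapse = ", "), call. = FALSE)
  }
  pos <- c("a1", "a2", "b1", "b2", "eps", "tau1", "tau2", "tau3")
  bad <- pos[vapply(pos, function(nm) vals[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("motif parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(c(vals, list(activations = activations)), class = "motif_params")
}

#' @export
print.motif_params <- function(x, ...) {
  cat("<motif_params> 2 neurons, 2 synapses, 1 astrocyte\n")
  nums <- unlist(x[setdiff(names(x), "activations")])
  print(nums)
  invisible(x)
}

#' Motif state vector
#'
#' @param x1,x2 neuron states (mean membrane potential, arbitrary units).
#' @param w1,w2 synaptic efficacies (signed).
#' @param z astrocyte calcium-wave activity surrogate.
#' @return A named numeric vector of class `motif_state`.
#' @export
motif_state <- function(x1 = 0, x2 = 0, w1 = 0, w2 = 0, z = 0) {
  s <- c(x1 = x1, x2 = x2, w1 = w1, w2 = w2, z = z)
  if (!all(is.finite(s))) stop("motif state must be finite", call. = FALSE)
  structure(s, class = c("motif_state", "numeric"))
}

#' Parameters of the full neuron-astrocyte hypernetwork
#'
#' Describes `n` neurons, `o` directed synapses (ordered neuron pairs, no
#' self-pairs) and `m` astrocytes. Each synapse `(i, j)` carries Hebbian
#' plasticity with gain `c` and receives meta-plastic drive `d * psi(z_k)`
#' from its assigned astrocyte `k`; each astrocyte senses the firing
#' correlation `phi(x_i) phi(x_j)` of one monitored synapse with gain `h`
#' and couples to other astrocytes through `f` (gap-junction-like
#' interactions).
#'
#' @param n,m neuron and astrocyte counts (`m <= o <= n (n - 1)`).
#' @param synapse_index integer matrix `o x 2` of ordered pairs `(i, j)`,
#'   meaning a synapse from neuron `j` onto neuron `i`; no self-pairs, no
#'   repeats; `o >= 1`.
#' @param a length-`n` positive neuron decay rates.
#' @param b,c,d length-`o` synapse decay rates (positive), Hebbian gains and
#'   astrocyte-coupling gains (both signed).
#' @param e length-`m` positive astrocyte decay rates.
#' @param f `m x m` astrocyte-astrocyte coupling matrix.
#' @param h length-`m` sensitivities to the monitored synaptic correlation.
#' @param synapse_astro length-`o` integer map: the astrocyte whose output
#'   `psi(z_k)` enters each synapse's `d * psi(z_k)` term.
#' @param astro_synapse length-`m` integer map: the synapse whose pair
#'   `(i, j)` enters each astrocyte's `h_k phi(x_i) phi(x_j)` term.
#' @param tau_n,tau_w,tau_a positive time constants with
#'   `tau_n <= tau_w <= tau_a`.
#' @param activations an [activation_triple()].
#'
#' @return An object of class `network_params`.
#' @export
network_params <- function(n, m, synapse_index,
                           a = rep(1, n), b = NULL, c = NULL, d = NULL,
                           e = rep(1, m), f = matrix(0, m, m), h = rep(0, m),
                           synapse_astro = NULL, astro_synapse = NULL,
                           tau_n = 0.01, tau_w = 0.01, tau_a = 1,
                           activations = activation_triple()) {
  synapse_index <- as.matrix(synapse_index)
  if (ncol(synapse_index) != 2) stop("synapse_index must be o x 2", call. = FALSE)
  o <- nrow(synapse_index)
  if (o < 1) stop("at least one synapse is required (o >= 1)", call. = FALSE)
  storage.mode(synapse_index) <- "integer"
  if (any(synapse_index < 1L) || any(synapse_index > n)) {
    stop("synapse_index refers to a nonexistent neuron", call. = FALSE)
  }
  if (any(synapse_index[, 1] == synapse_index[, 2])) {
    stop("self-pairs are not allowed in synapse_index", call. = FALSE)
  }
  if (anyDuplicated(synapse_index)) {
    stop("synapse_index contains repeated pairs", call. = FALSE)
  }
  if (!(m <= o && o <= n * (n - 1))) {
    stop("require m <= o <= n(n-1)", call. = FALSE)
  }
  if (is.null(b)) b <- rep(1, o)
  if (is.null(c)) c <- rep(0, o)
  if (is.null(d)) d <- rep(0, o)
  if (is.null(synapse_astro)) synapse_astro <- rep_len(seq_len(m), o)
  if (is.null(astro_synapse)) astro_synapse <- rep_len(seq_len(o), m)
  synapse_astro <- as.integer(synapse_astro)
  astro_synapse <- as.integer(astro_synapse)
  if (length(a) != n || length(e) != m || length(h) != m ||
      length(b) != o || length(c) != o || length(d) != o) {
    stop("parameter vector lengths inconsistent with n, m, o", call. = FALSE)
  }
  if (length(synapse_astro) != o || any(synapse_astro < 1L | synapse_astro > m)) {
    stop("synapse_astro must map each synapse to an existing astrocyte",
         call. = FALSE)
  }
  if (length(astro_synapse) != m || any(astro_synapse < 1L | astro_synapse > o)) {
    stop("astro_synapse must map each astrocyte to an existing synapse",
         call. = FALSE)
  }
  f <- as.matrix(f)
  if (!all(dim(f) == c(m, m))) stop("f must be m x m", call. = FALSE)
  if (any(c(a, b, e) <= 0)) stop("decay rates must be strictly positive", call. = FALSE)
  if (!(tau_n > 0 && tau_n <= tau_w && tau_w <= tau_a)) {
    stop("require 0 < tau_n <= tau_w <= tau_a", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m), o = o,
                 synapse_index = synapse_index,
                 a = a, b = b, c = c, d = d, e = e, f = f, h = h,
                 synapse_astro = synapse_astro, astro_synapse = astro_synapse,
                 tau_n = tau_n, tau_w = tau_w, tau_a = tau_a,
                 activations = activations),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> n = %d neurons, o = %d synapses, m = %d astrocytes\n",
              x$n, x$o, x$m))
  cat(sprintf("  tau_n = %g, tau_w = %g, tau_a = %g\n", x$tau_n, x$tau_w, x$tau_a))
  invisible(x)
}

#' Network state
#'
#' @param x length-`n` neuron vector.
#' @param W length-`o` synaptic efficacies (ordered as `synapse_index`).
#' @param z length-`m` astrocyte vector.
#' @return A list of class `network_state`.
#' @export
network_state <- function(x, W, z) {
  if (!all(is.finite(c(x, W, z)))) stop("network state must be finite", call. = FALSE)
  structure(list(x = as.numeric(x), W = as.numeric(W), z = as.numeric(z)),
            class = "network_state")
}

#' Read or write motif parameters as YAML or JSON
#'
#' Field names mirror the model symbols (`a1`, `c2`, `tau3`, ...). The
#' format is inferred from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_motif_params()` returns a [motif_params()] object;
#'   `write_motif_params()` returns `path` invisibly.
#' @export
read_motif_params <- function(path) {
  vals <- read_config(path)
  keep <- intersect(names(vals),
                    c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2",
                      "eps", "h", "tau1", "tau2", "tau3"))
  do.call(motif_params, vals[keep])
}

#' @rdname read_motif_params
#' @param params a [motif_params()] object.
#' @export
write_motif_params <- function(params, path) {
  vals <- params[setdiff(names(params), "activations")]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unrecognised config format (want .yaml/.yml/.json): ", path,
         call. = FALSE)
  }
}
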